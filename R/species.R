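# BLASTN-like nucleotide scoring used for fragment and 16S alignments
dna_submat <- function() {
  if (is.null(the_aln$DNAMAT)) {
    the_aln$DNAMAT <- Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = FALSE
    )
  }
  the_aln$DNAMAT
}

#' Fragment-based average nucleotide identity between two genomes
#'
#' ANIb-style ANI: the query genome is chopped into non-overlapping
#' fragments (1,020 bp by default; a terminal remainder of at least 100 bp
#' is kept), each fragment is anchored in the subject genome by exact k-mer
#' seeding (k = 15) on the best-supported diagonal, aligned
#' fragment-globally against the anchored window, and kept when it passes
#' the JSpecies-style filters (alignment coverage >= 70% of the fragment and
#' identity >= 30%). ANI is the mean percent identity over passing
#' fragments; `coverage` is the fraction of fragments passing. A fragment
#' with no seed in the subject fails, so unrelated genomes yield coverage
#' near 0 and ANI `NA`. ANI of a genome against itself is exactly 100.
#'
#' The measure is mildly asymmetric (fragments come from `a`);
#' [pairwise_ani()] averages the two directions before clustering.
#'
#' @param a,b `genome_record` objects with nucleotide contigs.
#' @param fragment_len Fragment length in bp.
#' @param k Seed k-mer length.
#' @return List with `ani` (percent, `NA` when no fragment passes),
#'   `coverage` (fraction of fragments passing) and `n_fragments`.
#' @export
compute_ani <- function(a, b, fragment_len = 1020L, k = 15L) {
  stopifnot(inherits(a, "genome_record"), inherits(b, "genome_record"))
  if (is.null(a$nucleotide) || is.null(b$nucleotide)) {
    abort("both genomes need nucleotide contigs for ANI")
  }
  if (sum(nchar(a$nucleotide)) < fragment_len) {
    abort(sprintf("genome %s (%d bp) is shorter than one %d bp fragment",
                  a$genome_id, sum(nchar(a$nucleotide)), fragment_len))
  }
  frags <- unlist(map(a$nucleotide, chop_fragments, fragment_len = fragment_len))
  if (!length(frags)) {
    abort(sprintf("genome %s is shorter than one %d bp fragment", a$genome_id,
                  fragment_len))
  }
  ids <- map_dbl(frags, fragment_identity, contigs = b$nucleotide, k = k)
  passing <- !is.na(ids)
  list(
    ani = if (any(passing)) mean(ids[passing]) else NA_real_,
    coverage = mean(passing),
    n_fragments = length(frags)
  )
}

chop_fragments <- function(contig, fragment_len, min_tail = 100L) {
  L <- nchar(contig)
  if (L < fragment_len) {
    return(if (L >= min_tail) contig else character())
  }
  starts <- seq(1L, L, by = fragment_len)
  frags <- substring(contig, starts, pmin(starts + fragment_len - 1L, L))
  frags[nchar(frags) >= min_tail | seq_along(frags) == 1L]
}

# identity (%) of one fragment against its best seeded window, or NA
fragment_identity <- function(frag, contigs, k, pad = 100L,
                              min_cov = 0.70, min_ident = 30) {
  flen <- nchar(frag)
  offs <- unique(c(seq(1L, flen - k + 1L, by = max(1L, k * 2L)), flen - k + 1L))
  seeds <- substring(frag, offs, offs + k - 1L)

  best <- NULL # list(contig, diag, votes)
  for (ctg in names(contigs)) {
    subj <- contigs[[ctg]]
    diags <- integer()
    for (si in seq_along(seeds)) {
      m <- gregexpr(seeds[[si]], subj, fixed = TRUE)[[1]]
      if (m[1] > 0L) diags <- c(diags, as.integer(m) - offs[[si]] + 1L)
    }
    if (!length(diags)) next
    bucket <- round(diags / 10) * 10L
    tab <- sort(table(bucket), decreasing = TRUE)
    top <- as.integer(names(tab)[tab == tab[[1]]])
    d <- min(top)
    if (is.null(best) || tab[[1]] > best$votes) {
      best <- list(contig = ctg, diag = d, votes = tab[[1]])
    }
  }
  if (is.null(best)) return(NA_real_)

  subj <- contigs[[best$contig]]
  w0 <- max(1L, best$diag - pad)
  w1 <- min(nchar(subj), best$diag + flen - 1L + pad)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(frag),
    Biostrings::DNAString(substr(subj, w0, w1)),
    type = "global-local", substitutionMatrix = dna_submat(),
    gapOpening = 5, gapExtension = 2
  )
  ncol <- nchar(as.character(Biostrings::alignedPattern(aln)))
  aligned <- flen / flen # pattern is globally aligned in global-local mode
  ident <- 100 * Biostrings::nmatch(aln) / ncol
  if (aligned < min_cov || ident < min_ident) return(NA_real_)
  ident
}

#' Pairwise 16S rRNA identity
#'
#' Ends-free (overlap) global alignment identity in percent: matches divided
#' by alignment columns, terminal gaps excluded, so a sequence compared with
#' its own prefix is scored over the overlapping region only. Sequences must
#' be IUPAC DNA. When `min_overlap > 0` and fewer alignment columns overlap,
#' `NA` is returned (fragmentary MAG 16S genes should not drive species
#' calls).
#'
#' @param a,b DNA sequences (character).
#' @param min_overlap Minimum alignment columns required; default 0.
#' @return Percent identity (or `NA`).
#' @examples
#' compute_16s_identity("ACGTACGT", "ACGTACGT")
#' @export
compute_16s_identity <- function(a, b, min_overlap = 0L) {
  if (!nchar(a) || !nchar(b)) abort("empty 16S sequence")
  sa <- try(Biostrings::DNAString(a), silent = TRUE)
  sb <- try(Biostrings::DNAString(b), silent = TRUE)
  if (inherits(sa, "try-error") || inherits(sb, "try-error")) {
    abort("16S sequences must be IUPAC DNA")
  }
  aln <- Biostrings::pairwiseAlignment(
    sa, sb, type = "overlap", substitutionMatrix = dna_submat(),
    gapOpening = 5, gapExtension = 2
  )
  ncol <- nchar(as.character(Biostrings::alignedPattern(aln)))
  if (ncol == 0L || ncol < min_overlap) return(NA_real_)
  100 * Biostrings::nmatch(aln) / ncol
}

#' Pairwise identity matrices over a genome set
#'
#' `pairwise_ani()` computes symmetric ANI values (mean of the two fragment
#' directions); `pairwise_16s()` computes 16S identities from each record's
#' `rrna16s` sequence, reporting `NA` for pairs overlapping fewer than
#' `min_overlap` columns.
#'
#' @param genomes List of `genome_record` objects.
#' @param ... Passed to [compute_ani()].
#' @param min_overlap See [compute_16s_identity()]; default 800 columns.
#' @return Tibble `genome_a`, `genome_b`, `value` (percent), plus `coverage`
#'   for ANI; one row per unordered pair including the diagonal (100).
#'   Attribute `kind` is `"ani"` or `"rrna16s"`.
#' @export
pairwise_ani <- function(genomes, ...) {
  genomes <- as_genome_list(genomes)
  ids <- names(genomes)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in i:length(ids)) {
      if (i == j) {
        rows[[length(rows) + 1L]] <- tibble(genome_a = ids[[i]], genome_b = ids[[j]],
                                            value = 100, coverage = 1)
        next
      }
      ab <- compute_ani(genomes[[i]], genomes[[j]], ...)
      ba <- compute_ani(genomes[[j]], genomes[[i]], ...)
      vals <- c(ab$ani, ba$ani)
      rows[[length(rows) + 1L]] <- tibble(
        genome_a = ids[[i]], genome_b = ids[[j]],
        value = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
        coverage = mean(c(ab$coverage, ba$coverage))
      )
    }
  }
  out <- list_rbind(rows)
  attr(out, "kind") <- "ani"
  out
}

#' @rdname pairwise_ani
#' @export
pairwise_16s <- function(genomes, min_overlap = 800L) {
  genomes <- as_genome_list(genomes)
  has16 <- map_lgl(genomes, function(g) !is.null(g$rrna16s))
  if (!all(has16)) {
    abort(paste0("genome(s) without 16S sequence: ",
                 paste(names(genomes)[!has16], collapse = ", ")))
  }
  ids <- names(genomes)
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in i:length(ids)) {
      v <- if (i == j) 100 else {
        compute_16s_identity(genomes[[i]]$rrna16s, genomes[[j]]$rrna16s,
                             min_overlap = min_overlap)
      }
      rows[[length(rows) + 1L]] <- tibble(genome_a = ids[[i]],
                                          genome_b = ids[[j]], value = v)
    }
  }
  out <- list_rbind(rows)
  attr(out, "kind") <- "rrna16s"
  out
}

#' Delineate species by single-linkage clustering
#'
#' Species are the connected components of the graph whose edges are genome
#' pairs with identity at or above the cutoff (boundary inclusive: a pair at
#' exactly 95.0 ANI is conspecific). `NA` pairs contribute no edge. Every
#' unordered pair of genomes must be present in the matrix.
#'
#' @param pm Pairwise tibble from [pairwise_ani()] or [pairwise_16s()].
#' @param cutoff Percent identity cutoff; defaults to 95 for ANI and 98.65
#'   for 16S by matrix kind.
#' @return A `species_clusters` object: tibble `genome_id`, `species_id`
#'   with attributes `method` and `cutoff`; has [tidy()] and [glance()]
#'   methods.
#' @examples
#' pm <- tibble::tibble(
#'   genome_a = c("g1", "g1", "g2"), genome_b = c("g2", "g3", "g3"),
#'   value = c(99, 85, 85)
#' )
#' delineate_species(pm, cutoff = 95)
#' @export
delineate_species <- function(pm, cutoff = NULL) {
  kind <- attr(pm, "kind") %||% "ani"
  if (is.null(cutoff)) {
    cutoff <- if (kind == "rrna16s") default_thresholds()$rrna_species_cutoff
              else default_thresholds()$ani_species_cutoff
  }
  ids <- sort(unique(c(pm$genome_a, pm$genome_b)))
  off_diag <- pm[pm$genome_a != pm$genome_b, , drop = FALSE]
  have <- paste(pmin(off_diag$genome_a, off_diag$genome_b),
                pmax(off_diag$genome_a, off_diag$genome_b))
  need <- utils::combn(ids, 2L)
  need <- paste(pmin(need[1, ], need[2, ]), pmax(need[1, ], need[2, ]))
  missing_pairs <- setdiff(need, have)
  if (length(missing_pairs)) {
    abort(paste0("pairwise matrix is missing pair(s): ",
                 paste(head(missing_pairs, 5L), collapse = "; ")))
  }
  edges <- off_diag[!is.na(off_diag$value) & off_diag$value >= cutoff, , drop = FALSE]
  gr <- igraph::graph_from_data_frame(edges[c("genome_a", "genome_b")],
                                      directed = FALSE,
                                      vertices = data.frame(name = ids))
  comp <- igraph::components(gr)$membership
  # number species by their first genome in sorted id order
  first_seen <- unique(comp[ids])
  relabel <- setNames(seq_along(first_seen), first_seen)
  out <- tibble(genome_id = ids,
                species_id = sprintf("sp_%02d", relabel[as.character(comp[ids])]))
  structure(out, class = c("species_clusters", class(out)),
            method = kind, cutoff = cutoff)
}

#' @export
print.species_clusters <- function(x, ...) {
  cat(sprintf("<species_clusters> %d genomes -> %d species (%s >= %s)\n",
              nrow(x), length(unique(x$species_id)), attr(x, "method"),
              format(attr(x, "cutoff"))))
  NextMethod()
}

#' @rdname delineate_species
#' @param x,object A `species_clusters` object.
#' @param ... Unused.
#' @export
tidy.species_clusters <- function(x, ...) {
  tibble(genome_id = x$genome_id, species_id = x$species_id,
         method = attr(x, "method"), cutoff = attr(x, "cutoff"))
}

#' @rdname delineate_species
#' @export
glance.species_clusters <- function(x, ...) {
  tibble(n_genomes = nrow(x), n_species = length(unique(x$species_id)),
         largest_species = max(table(x$species_id)),
         method = attr(x, "method"), cutoff = attr(x, "cutoff"))
}

#' Disagreement pairs between two species partitions
#'
#' The ANI and 16S partitions are reported side by side rather than merged;
#' this lists the genome pairs grouped together under one method but split
#' under the other.
#'
#' @param a,b Two `species_clusters` objects over the same genomes.
#' @return Tibble `genome_a`, `genome_b`, `together_a`, `together_b`.
#' @export
species_disagreements <- function(a, b) {
  ids <- sort(a$genome_id)
  if (!setequal(ids, b$genome_id)) abort("partitions cover different genomes")
  ma <- setNames(a$species_id, a$genome_id)
  mb <- setNames(b$species_id, b$genome_id)
  prs <- utils::combn(ids, 2L)
  same_a <- ma[prs[1, ]] == ma[prs[2, ]]
  same_b <- mb[prs[1, ]] == mb[prs[2, ]]
  disagree <- same_a != same_b
  tibble(genome_a = prs[1, disagree], genome_b = prs[2, disagree],
         together_a = unname(same_a[disagree]), together_b = unname(same_b[disagree]))
}

#' Write a square identity matrix TSV
#'
#' @param pm Pairwise tibble from [pairwise_ani()] or [pairwise_16s()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_identity_matrix <- function(pm, path) {
  both <- bind_rows(
    pm[c("genome_a", "genome_b", "value")],
    pm[pm$genome_a != pm$genome_b, ] |>
      select(genome_a = "genome_b", genome_b = "genome_a", "value")
  )
  wide <- both |>
    arrange(.data$genome_a, .data$genome_b) |>
    pivot_wider(names_from = "genome_b", values_from = "value")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}
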