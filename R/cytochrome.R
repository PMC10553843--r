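#' Count CxxCH heme-binding motifs in a protein
#'
#' c-type cytochromes bind heme covalently through the CxxCH motif, so the
#' motif count is a direct census of heme-binding capacity. The scan slides
#' over every 5-residue window; overlapping occurrences are all counted
#' (lookahead semantics), since closely spaced heme motifs can share a
#' cysteine. `X` is treated as an unknown residue: it may sit in a wildcard
#' position but never matches the literal C or H of the motif.
#'
#' @param seq Uppercase amino-acid string (20 standard letters plus `X`).
#' @param motif Motif in x-notation; `x` matches any residue. Default
#'   `"CxxCH"`. Variants such as `"CxxxCH"` can be scanned by passing them
#'   here.
#' @return List with `heme_count` (integer) and `motif_positions` (1-based
#'   start positions, sorted).
#' @examples
#' count_heme_motifs("MKCAACHLLCPKCHGG")
#' count_heme_motifs("CAACHACH") # overlapping motifs share the C at position 4
#' @export
count_heme_motifs <- function(seq, motif = "CxxCH") {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (is.na(seq)) abort("sequence is NA")
  if (grepl("[^A-Z]", seq)) {
    abort("sequence contains non-alphabetic or lowercase characters")
  }
  pattern <- paste0("(?=", gsub("x", "[A-Z]", motif, fixed = TRUE), ")")
  if (nchar(seq) == 0L) {
    return(list(heme_count = 0L, motif_positions = integer()))
  }
  m <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  pos <- as.integer(m[m > 0L])
  list(heme_count = length(pos), motif_positions = sort(pos))
}

#' Classify a cytochrome by heme count
#'
#' Implements the census categories: 0 motifs is not a cytochrome; 1-3 is an
#' ordinary cytochrome c; at least `multiheme_min` (default 4) is multiheme;
#' strictly more than `conduit_min_exclusive` (default 5) additionally
#' qualifies as a conduit candidate — the class searched for beta-barrel
#' neighbors. The boundaries are inclusive at 4 and strict at 5, so a 5-heme
#' protein is multiheme but never a conduit candidate under defaults.
#'
#' @param heme_count Integer vector of motif counts (>= 0).
#' @param thresholds A [default_thresholds()] bundle.
#' @return Character vector over
#'   `{"none","cytochrome","multiheme","conduit_candidate"}`.
#' @examples
#' classify_cytochrome(c(0, 3, 4, 5, 6))
#' @export
classify_cytochrome <- function(heme_count, thresholds = default_thresholds()) {
  heme_count <- as.integer(heme_count)
  if (anyNA(heme_count) || any(heme_count < 0L)) {
    abort("heme_count must be non-negative integers")
  }
  dplyr::case_when(
    heme_count > thresholds$conduit_min_exclusive ~ "conduit_candidate",
    heme_count >= thresholds$multiheme_min ~ "multiheme",
    heme_count >= 1L ~ "cytochrome",
    TRUE ~ "none"
  )
}

cytochrome_categories <- c("none", "cytochrome", "multiheme", "conduit_candidate")

#' Scan genomes for c-type cytochromes
#'
#' Runs the CxxCH census over every protein of one or more genomes and
#' returns one row per protein with at least one motif, in deterministic
#' (genome, contig, gene_index) order. When a localization prediction table
#' is supplied its labels are joined onto the calls.
#'
#' @param genomes A `genome_record` or list of them.
#' @param thresholds A [default_thresholds()] bundle.
#' @param localization Optional localization table from
#'   [read_prediction_table()].
#' @param motif Motif in x-notation, see [count_heme_motifs()].
#' @return Tibble: `genome_id`, `contig_id`, `gene_index`, `gene_id`,
#'   `heme_count`, `motif_positions` (comma-joined), `category`,
#'   `localization`.
#' @export
scan_cytochromes <- function(genomes, thresholds = default_thresholds(),
                             localization = NULL, motif = "CxxCH") {
  genomes <- as_genome_list(genomes)
  rows <- map(genomes, function(g) {
    counts <- map(g$proteins, count_heme_motifs, motif = motif)
    hc <- unname(map_int(counts, "heme_count"))
    keep <- hc >= 1L
    if (!any(keep)) return(NULL)
    tibble(
      genome_id = g$genome_id,
      gene_id = names(g$proteins)[keep],
      heme_count = hc[keep],
      motif_positions = unname(map_chr(counts[keep], function(x) {
        paste(x$motif_positions, collapse = ",")
      }))
    ) |>
      left_join(g$genes[c("gene_id", "contig_id", "gene_index")], by = "gene_id")
  })
  calls <- list_rbind(compact(rows))
  if (nrow(calls) == 0L) {
    calls <- tibble(genome_id = character(), contig_id = character(),
                    gene_index = integer(), gene_id = character(),
                    heme_count = integer(), motif_positions = character())
  }
  calls <- calls |>
    mutate(category = classify_cytochrome(.data$heme_count, thresholds)) |>
    arrange(.data$genome_id, .data$contig_id, .data$gene_index)
  if (!is.null(localization)) {
    calls <- left_join(calls,
                       setNames(localization[c("gene_id", "label")],
                                c("gene_id", "localization")),
                       by = "gene_id")
  } else {
    calls$localization <- NA_character_
  }
  calls[c("genome_id", "contig_id", "gene_index", "gene_id", "heme_count",
          "motif_positions", "category", "localization")]
}

#' Cluster cytochrome calls into sequence types
#'
#' Deterministic stand-in for by-eye alignment typing: greedy centroid
#' clustering. Sequences are processed longest first (ties by gene_id); each
#' sequence joins the earliest-founded centroid whose global-alignment
#' identity (matches / alignment columns) reaches `identity_cutoff`,
#' otherwise it founds a new type with itself as representative. The result
#' is invariant to the order of the input rows because the processing order
#' is recomputed internally.
#'
#' A coarse functional role is attached per type from the representative's
#' localization label when available: extracellular -> `EET`, periplasmic ->
#' `periplasmic_carrier`, membrane -> `inner_membrane`, otherwise
#' `unassigned`.
#'
#' @param calls Cytochrome call tibble from [scan_cytochromes()]; `gene_id`
#'   must be unique across the set.
#' @param proteins Named character vector of the corresponding protein
#'   sequences (names are gene ids).
#' @param identity_cutoff Global-alignment identity in (0,1); default 0.5.
#' @return Tibble: `gene_id`, `type_id`, `representative`, `role_class`.
#' @export
cluster_cytochrome_types <- function(calls, proteins, identity_cutoff = 0.5) {
  if (!(identity_cutoff > 0 && identity_cutoff < 1)) {
    abort("identity_cutoff must lie in (0, 1)")
  }
  if (nrow(calls) == 0L) {
    return(tibble(gene_id = character(), type_id = character(),
                  representative = character(), role_class = character()))
  }
  if (anyDuplicated(calls$gene_id)) abort("gene_id must be unique across calls")
  missing_seq <- setdiff(calls$gene_id, names(proteins))
  if (length(missing_seq)) {
    abort(paste0("no sequence for call(s): ", paste(missing_seq, collapse = ", ")))
  }
  seqs <- proteins[calls$gene_id]
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]

  centroids <- character()
  assignment <- character(length(seqs))
  names(assignment) <- names(seqs)
  for (id in names(seqs)) {
    joined <- FALSE
    for (ci in seq_along(centroids)) {
      if (global_identity(seqs[[id]], proteins[[centroids[[ci]]]]) >= identity_cutoff) {
        assignment[[id]] <- centroids[[ci]]
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      centroids <- c(centroids, id)
      assignment[[id]] <- id
    }
  }

  type_ids <- setNames(sprintf("type_%03d", seq_along(centroids)), centroids)
  out <- tibble(
    gene_id = names(assignment),
    type_id = unname(type_ids[assignment]),
    representative = unname(assignment)
  )
  loc <- setNames(calls$localization, calls$gene_id)
  role_of <- function(rep_id) {
    lab <- loc[[rep_id]] %||% NA_character_
    if (is.na(lab)) return("unassigned")
    switch(lab,
           extracellular = "EET",
           periplasmic = "periplasmic_carrier",
           membrane = "inner_membrane",
           "unassigned")
  }
  out$role_class <- map_chr(out$representative, role_of)
  arrange(out, .data$type_id, .data$gene_id)
}

# global (Needleman-Wunsch) identity: matches / alignment columns
global_identity <- function(a, b) {
  st <- nw_stats(a, b, blosum62(), 11, 1)
  if (st$columns[1] == 0L) return(0)
  st$nmatch[1] / st$columns[1]
}

as_genome_list <- function(genomes) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!length(genomes) || !all(map_lgl(genomes, inherits, "genome_record"))) {
    abort("`genomes` must be a genome_record or a list of genome_record objects")
  }
  names(genomes) <- map_chr(genomes, "genome_id")
  genomes
}
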