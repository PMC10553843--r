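#' Define a trait for presence/absence searching
#'
#' A trait is one or more query protein sequences plus the decision
#' thresholds of the homology search that declares it present in a genome:
#' an E-value cutoff (1e-30 for conduit components, 1e-5 for ordinary traits)
#' and a minimum fraction of the query that must be aligned.
#'
#' @param trait_id Identifier.
#' @param query_sequences Character vector of amino-acid query sequences
#'   (at least one); presence is an OR over queries.
#' @param evalue_cutoff Positive E-value cutoff.
#' @param min_query_coverage Fraction of query residues that must be covered
#'   by the best local alignment; 0 disables the requirement.
#' @return A `trait_definition` list.
#' @export
trait_definition <- function(trait_id, query_sequences,
                             evalue_cutoff = default_thresholds()$evalue_loose,
                             min_query_coverage = 0.5) {
  if (!length(query_sequences)) abort("trait needs at least one query sequence")
  if (any(!nchar(query_sequences))) abort("empty query sequence")
  if (evalue_cutoff <= 0) abort("evalue_cutoff must be positive")
  if (min_query_coverage < 0 || min_query_coverage > 1) {
    abort("min_query_coverage must lie in [0, 1]")
  }
  structure(list(trait_id = trait_id,
                 query_sequences = unname(query_sequences),
                 evalue_cutoff = evalue_cutoff,
                 min_query_coverage = min_query_coverage),
            class = "trait_definition")
}

#' Search one genome for one trait
#'
#' Local-aligns every query of the trait against every protein of the
#' genome, converts the optimal scores to Karlin-Altschul E-values against
#' the genome's total proteome length, and declares the trait present iff
#' the best hit — the lowest-E (query, protein) pair — satisfies both the
#' E-value cutoff and the query-coverage floor. The best hit is returned
#' with its statistics either way.
#'
#' @param trait A [trait_definition()].
#' @param genome A `genome_record`.
#' @return List with `present` (logical) and `best_hit` (one-row tibble:
#'   `trait_id`, `genome_id`, `gene_id`, `score`, `bit_score`, `evalue`,
#'   `identity`, `query_coverage`, `present`; or NULL when nothing aligned
#'   with positive score).
#' @export
search_trait <- function(trait, genome) {
  stopifnot(inherits(trait, "trait_definition"), inherits(genome, "genome_record"))
  res <- search_trait_batch(trait, as_genome_list(genome))[[1]]
  res
}

# one trait against many genomes with a single vectorised scoring pass per
# query; decision logic is shared with search_trait (which wraps this)
search_trait_batch <- function(trait, genomes) {
  sizes <- map_int(genomes, ~ length(.x$proteins))
  if (any(sizes == 0L)) {
    abort(paste0("genome(s) with an empty proteome: ",
                 paste(names(genomes)[sizes == 0L], collapse = ", ")))
  }
  all_prots <- unlist(unname(map(genomes, "proteins")))
  owner <- rep(names(genomes), sizes)
  n_db <- map_dbl(genomes, ~ sum(nchar(.x$proteins)))

  # per-protein best (score, evalue, query) over all queries of the trait
  best_sc <- rep(0, length(all_prots))
  best_ev <- rep(Inf, length(all_prots))
  best_q <- rep(NA_character_, length(all_prots))
  for (q in trait$query_sequences) {
    sc <- local_scores(q, all_prots)
    ev <- estimate_evalue(sc, m = nchar(q), n = n_db[owner])
    better <- ev < best_ev & sc > 0
    best_sc[better] <- sc[better]
    best_ev[better] <- ev[better]
    best_q[better] <- q
  }

  # the decision hit per genome is the best (lowest-E) hit; only that pair
  # needs the full alignment for identity and query coverage
  cand <- list()
  for (gid in names(genomes)) {
    in_g <- which(owner == gid & best_sc > 0)
    if (!length(in_g)) next
    cand[[gid]] <- in_g[which.min(best_ev[in_g])]
  }
  idx <- unlist(cand, use.names = FALSE)
  stats <- list()
  if (length(idx)) {
    # one vectorised full-alignment pass per distinct query
    ident <- numeric(length(idx)); cover <- numeric(length(idx))
    for (q in unique(best_q[idx])) {
      sel <- which(best_q[idx] == q)
      st <- local_stats(q, all_prots[idx[sel]])
      ident[sel] <- ifelse(st$columns > 0, st$nmatch / pmax(st$columns, 1L), 0)
      cover[sel] <- st$q_aligned / nchar(q)
    }
    stats <- setNames(map(seq_along(idx), function(k) {
      list(identity = ident[[k]], coverage = cover[[k]])
    }), as.character(idx))
  }

  map(names(genomes), function(gid) {
    i <- cand[[gid]]
    if (is.null(i)) return(list(present = FALSE, best_hit = NULL))
    st <- stats[[as.character(i)]]
    present <- best_ev[[i]] <= trait$evalue_cutoff &&
      st$coverage >= trait$min_query_coverage
    row <- tibble(trait_id = trait$trait_id, genome_id = gid,
                  gene_id = names(all_prots)[[i]],
                  score = best_sc[[i]], bit_score = bit_score(best_sc[[i]]),
                  evalue = best_ev[[i]], identity = st$identity,
                  query_coverage = st$coverage, present = present)
    list(present = present, best_hit = row)
  }) |> setNames(names(genomes))
}

#' Build the traits-by-genomes presence/absence matrix
#'
#' Runs [search_trait()] for every (trait, genome) pair and aggregates to
#' the study's group-level presence calls: for each syntrophic clade the
#' fraction of its member genomes carrying the trait, and for each order the
#' *background* fraction computed over non-syntrophic members only. A trait
#' counts as present at group level iff its fraction is strictly greater
#' than `background_presence_frac` (the ">30%" rule; 3 of 10 is absent, 4 of
#' 10 is present).
#'
#' @param traits List of [trait_definition()] objects.
#' @param genomes List of `genome_record` objects with taxonomy labels.
#' @param thresholds A [default_thresholds()] bundle.
#' @return A `trait_matrix` object: list with `presence` (logical matrix,
#'   traits x genomes), `hits` (per-pair best hits tibble), `fractions`
#'   (group-level tibble), `taxonomy`, `thresholds`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
build_trait_matrix <- function(traits, genomes, thresholds = default_thresholds()) {
  genomes <- as_genome_list(genomes)
  if (!length(traits)) abort("no traits supplied")
  if (!all(map_lgl(traits, inherits, "trait_definition"))) {
    abort("`traits` must be a list of trait_definition objects")
  }
  names(traits) <- map_chr(traits, "trait_id")

  taxonomy <- tibble(
    genome_id = map_chr(genomes, "genome_id"),
    order = map_chr(genomes, ~ .x$taxonomy$order %||% NA_character_),
    clade = map_chr(genomes, ~ .x$taxonomy$clade %||% NA_character_),
    is_syntrophic = map_lgl(genomes, ~ isTRUE(.x$taxonomy$is_syntrophic))
  )
  if (anyNA(taxonomy$order) || anyNA(taxonomy$clade)) {
    abort("every genome needs order and clade labels")
  }

  res <- map(traits, function(tr) search_trait_batch(tr, genomes))
  presence <- vapply(res, function(per_genome) {
    map_lgl(per_genome, "present")
  }, logical(length(genomes)))
  presence <- t(presence) # traits x genomes
  dimnames(presence) <- list(names(traits), names(genomes))

  hits <- list_rbind(compact(map(res, function(per_genome) {
    list_rbind(compact(map(per_genome, "best_hit")))
  })))

  fractions <- presence_fractions(presence, taxonomy, thresholds)

  structure(list(presence = presence, hits = hits, fractions = fractions,
                 taxonomy = taxonomy, thresholds = thresholds),
            class = "trait_matrix")
}

# clade fractions over all clade members; order background over
# non-syntrophic members only, strict > rule for group presence
presence_fractions <- function(presence, taxonomy, thresholds) {
  long <- as_tibble(presence, rownames = "trait_id") |>
    pivot_longer(-"trait_id", names_to = "genome_id", values_to = "present") |>
    left_join(taxonomy, by = "genome_id")

  clades <- taxonomy |> count(.data$clade)
  if (any(clades$n == 0L)) abort("clade with zero genomes")

  clade_frac <- long |>
    group_by(.data$trait_id, group = .data$clade) |>
    summarise(order = .data$order[1], n_genomes = n(),
              fraction = mean(.data$present), .groups = "drop") |>
    mutate(group_kind = "clade")

  bg <- long |> filter(!.data$is_syntrophic)
  bg_orders <- setdiff(unique(taxonomy$order), unique(bg$order))
  if (length(bg_orders)) {
    warn(paste0("order(s) with no non-syntrophic members, background undefined: ",
                paste(bg_orders, collapse = ", ")))
  }
  order_frac <- bg |>
    group_by(.data$trait_id, group = .data$order) |>
    summarise(order = .data$order[1], n_genomes = n(),
              fraction = mean(.data$present), .groups = "drop") |>
    mutate(group_kind = "order_background")

  bind_rows(clade_frac, order_frac) |>
    mutate(present = .data$fraction > thresholds$background_presence_frac) |>
    select("trait_id", "group_kind", "group", "order", "n_genomes",
           "fraction", "present") |>
    arrange(.data$group_kind, .data$trait_id, .data$group)
}

#' @export
print.trait_matrix <- function(x, ...) {
  cat(sprintf("<trait_matrix> %d traits x %d genomes; %d present calls\n",
              nrow(x$presence), ncol(x$presence), sum(x$presence)))
  invisible(x)
}

#' @rdname build_trait_matrix
#' @param x,object A `trait_matrix`.
#' @param ... Unused.
#' @export
tidy.trait_matrix <- function(x, ...) {
  as_tibble(x$presence, rownames = "trait_id") |>
    pivot_longer(-"trait_id", names_to = "genome_id", values_to = "present") |>
    left_join(x$taxonomy, by = "genome_id")
}

#' @rdname build_trait_matrix
#' @export
glance.trait_matrix <- function(x, ...) {
  tibble(n_traits = nrow(x$presence), n_genomes = ncol(x$presence),
         n_present = sum(x$presence),
         presence_rate = mean(x$presence),
         n_clades = sum(x$fractions$group_kind == "clade") / max(1L, nrow(x$presence)),
         background_presence_frac = x$thresholds$background_presence_frac)
}

#' @rdname build_trait_matrix
#' @export
autoplot.trait_matrix <- function(object, ...) {
  tidy(object) |>
    ggplot(aes(x = .data$genome_id, y = .data$trait_id, fill = .data$present)) +
    geom_tile(color = "grey85") +
    scale_fill_manual(values = c(`TRUE` = "#2c7fb8", `FALSE` = "grey95")) +
    labs(x = NULL, y = NULL, fill = "present") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
}

#' Write / read trait matrix tables
#'
#' `write_trait_matrix()` emits the 0/1 presence matrix (traits as rows,
#' genomes as columns), the per-hit statistics and the group-level fractions
#' as TSVs next to each other.
#'
#' @param tm A `trait_matrix`.
#' @param dir Output directory.
#' @return Invisible character vector of the files written.
#' @export
write_trait_matrix <- function(tm, dir) {
  stopifnot(inherits(tm, "trait_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat_path <- file.path(dir, "trait_matrix.tsv")
  hits_path <- file.path(dir, "trait_hits.tsv")
  frac_path <- file.path(dir, "trait_fractions.tsv")
  m <- as_tibble(tm$presence * 1L, rownames = "trait_id")
  readr::write_tsv(m, mat_path, progress = FALSE)
  readr::write_tsv(tm$hits, hits_path, progress = FALSE)
  readr::write_tsv(tm$fractions, frac_path, progress = FALSE)
  invisible(c(mat_path, hits_path, frac_path))
}

#' Read trait definitions from a directory
#'
#' Expects one FASTA per trait named `<trait_id>.faa`, optionally with a
#' `traits.yaml` manifest giving per-trait `evalue_cutoff` and
#' `min_query_coverage`.
#'
#' @param dir Directory of trait FASTA files.
#' @return List of [trait_definition()] objects.
#' @export
read_trait_definitions <- function(dir) {
  faa <- sort(list.files(dir, pattern = "\\.faa$", full.names = TRUE))
  if (!length(faa)) abort(paste0("no .faa trait files in ", dir))
  manifest <- list()
  ypath <- file.path(dir, "traits.yaml")
  if (file.exists(ypath)) manifest <- yaml::read_yaml(ypath)
  map(faa, function(f) {
    tid <- sub("\\.faa$", "", basename(f))
    aa <- Biostrings::readAAStringSet(f)
    m <- manifest[[tid]] %||% list()
    trait_definition(
      tid, as.character(aa),
      evalue_cutoff = m$evalue_cutoff %||% default_thresholds()$evalue_loose,
      min_query_coverage = m$min_query_coverage %||% 0.5
    )
  })
}
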