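#' Call porin:cytochrome EET conduit clusters
#'
#' Applies the neighborhood rule for outer-membrane electron conduits: an
#' outer-membrane beta-barrel (porin) with at least one multiheme cytochrome
#' carrying strictly more than `conduit_min_exclusive` CxxCH motifs within
#' `neighborhood_window` genes (gene-index distance, same contig, strand
#' ignored, boundary inclusive at 10 under defaults). Clusters are anchored
#' on barrels — one cluster per qualifying barrel — so several cytochromes
#' flanking one porin are reported once; a cytochrome may appear in more than
#' one cluster when two barrels share its window. Genes absent from the
#' barrel table are treated as `not_barrel`.
#'
#' @param genomes A `genome_record` or list of them.
#' @param calls Cytochrome calls from [scan_cytochromes()] for the same
#'   genomes.
#' @param barrels Beta-barrel prediction table from
#'   [read_prediction_table()] (or [predict_barrels()] for synthetic data).
#' @param thresholds A [default_thresholds()] bundle.
#' @return Tibble: `genome_id`, `contig_id`, `barrel_gene`,
#'   `cytochrome_genes` (comma-joined), `n_cytochromes`, `min_distance`,
#'   `span_start`, `span_end`.
#' @export
find_conduit_clusters <- function(genomes, calls, barrels,
                                  thresholds = default_thresholds()) {
  genomes <- as_genome_list(genomes)
  empty <- tibble(genome_id = character(), contig_id = character(),
                  barrel_gene = character(), cytochrome_genes = character(),
                  n_cytochromes = integer(), min_distance = integer(),
                  span_start = integer(), span_end = integer())
  if (nrow(calls) == 0L || nrow(barrels) == 0L) return(empty)
  barrel_ids <- barrels$gene_id[barrels$label == "barrel"]
  cand <- calls[calls$heme_count > thresholds$conduit_min_exclusive, , drop = FALSE]
  if (!length(barrel_ids) || nrow(cand) == 0L) return(empty)

  out <- map(genomes, function(g) {
    gt <- g$genes
    b <- gt[gt$gene_id %in% barrel_ids, , drop = FALSE]
    cy <- cand[cand$genome_id == g$genome_id, , drop = FALSE]
    if (nrow(b) == 0L || nrow(cy) == 0L) return(NULL)
    cy <- left_join(cy[c("gene_id", "heme_count")],
                    gt[c("gene_id", "contig_id", "gene_index", "start", "end")],
                    by = "gene_id")
    rows <- pmap(b[c("gene_id", "contig_id", "gene_index", "start", "end")],
                 function(gene_id, contig_id, gene_index, start, end) {
      near <- cy[cy$contig_id == contig_id &
                   abs(cy$gene_index - gene_index) <= thresholds$neighborhood_window, ,
                 drop = FALSE]
      if (nrow(near) == 0L) return(NULL)
      near <- arrange(near, .data$gene_index)
      tibble(
        genome_id = g$genome_id,
        contig_id = contig_id,
        barrel_gene = gene_id,
        cytochrome_genes = paste(near$gene_id, collapse = ","),
        n_cytochromes = nrow(near),
        min_distance = min(abs(near$gene_index - gene_index)),
        span_start = min(start, near$start),
        span_end = max(end, near$end)
      )
    })
    list_rbind(compact(rows))
  })
  res <- list_rbind(compact(out))
  if (nrow(res) == 0L) return(empty)
  arrange(res, .data$genome_id, .data$contig_id, .data$barrel_gene)
}

#' Heuristic beta-barrel prediction for synthetic proteomes
#'
#' A coarse outer-membrane beta-barrel screen used when no external
#' prediction table exists (synthetic tests): length >= 300 residues,
#' C-terminal residue among F/W/Y (the terminal aromatic of bacterial OMP
#' barrels), and a sustained period-2 (alternating-hydrophobicity)
#' Kyte-Doolittle signature: at least `min_alternating_windows` 10-residue
#' windows, covering at least `min_alternating_frac` of all windows, must
#' show the same hydrophobic phase. It is a screen for simulated barrels,
#' not a re-implementation of a trained predictor.
#'
#' @param genomes A `genome_record` or list of them.
#' @param min_length Minimum length in residues.
#' @param min_alternating_windows Required count of period-2 windows.
#' @param min_alternating_frac Required fraction of windows in the dominant
#'   phase.
#' @return Prediction table tibble (`gene_id`, `label`, `score`).
#' @export
predict_barrels <- function(genomes, min_length = 300L,
                            min_alternating_windows = 8L,
                            min_alternating_frac = 0.3) {
  genomes <- as_genome_list(genomes)
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
          G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
          P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
  rows <- map(genomes, function(g) {
    tibble(
      gene_id = names(g$proteins),
      label = map_chr(g$proteins, function(s) {
        L <- nchar(s)
        if (L < min_length) return("not_barrel")
        if (!substr(s, L, L) %in% c("F", "W", "Y")) return("not_barrel")
        h <- kd[strsplit(s, "")[[1]]]
        # period-2 score of a 10-residue window: odd vs even positions,
        # tracking the hydrophobic phase so random spikes do not accumulate
        win <- 10L
        nwin <- L - win + 1L
        pos_phase <- 0L
        neg_phase <- 0L
        idx <- seq_len(win)
        odd <- idx[idx %% 2L == 1L]
        even <- idx[idx %% 2L == 0L]
        for (i in seq_len(nwin)) {
          w <- h[i:(i + win - 1L)]
          d <- mean(w[odd]) - mean(w[even])
          if (d > 2.5) pos_phase <- pos_phase + 1L
          if (d < -2.5) neg_phase <- neg_phase + 1L
        }
        alt <- max(pos_phase, neg_phase)
        if (alt >= min_alternating_windows && alt / nwin >= min_alternating_frac)
          "barrel" else "not_barrel"
      }),
      score = NA_real_
    )
  })
  out <- list_rbind(rows)
  attr(out, "kind") <- "beta_barrel"
  out
}

#' Define an operon-cassette matching rule
#'
#' @param rule_id Identifier.
#' @param required_categories Named list of keyword vectors; every category
#'   must be hit by at least one gene of a cassette.
#' @param optional_categories Named list of keyword vectors; hits are
#'   reported but not required.
#' @param max_gap Maximum number of non-category genes between consecutive
#'   category genes in one cassette.
#' @param min_genes Minimum number of category-hitting genes.
#' @return A `cassette_rule` list.
#' @export
cassette_rule <- function(rule_id, required_categories,
                          optional_categories = list(),
                          max_gap = 2L, min_genes = length(required_categories)) {
  if (!length(required_categories)) {
    abort("cassette rule needs at least one required category")
  }
  if (is.null(names(required_categories)) || any(names(required_categories) == "")) {
    abort("required_categories must be a named list of keyword vectors")
  }
  if (max_gap < 0L) abort("max_gap must be >= 0")
  if (min_genes < length(required_categories)) {
    abort("min_genes must be >= the number of required categories")
  }
  structure(list(rule_id = rule_id,
                 required_categories = required_categories,
                 optional_categories = optional_categories,
                 max_gap = as.integer(max_gap),
                 min_genes = as.integer(min_genes)),
            class = "cassette_rule")
}

#' Match operon cassettes against annotated gene runs
#'
#' Used for polysaccharide biosynthesis loci: a cassette hit is a maximal run
#' of genes on one contig in which consecutive category-hitting genes are at
#' most `max_gap` genes apart and every required category (e.g., glycosyl
#' transferase, sugar transporter/flippase, polysaccharide biosynthesis
#' protein) is hit at least once. Category membership is case-insensitive
#' substring matching of the rule's keywords against each gene's product
#' description.
#'
#' @param genomes A `genome_record` or list of them.
#' @param rule A [cassette_rule()].
#' @return Tibble: `genome_id`, `contig_id`, `rule_id`, `genes`
#'   (comma-joined category-hitting genes), `n_genes`, `categories_hit`,
#'   `span_start`, `span_end`.
#' @export
match_cassettes <- function(genomes, rule) {
  stopifnot(inherits(rule, "cassette_rule"))
  genomes <- as_genome_list(genomes)
  cats <- c(rule$required_categories, rule$optional_categories)
  rows <- map(genomes, function(g) {
    gt <- g$genes
    hit_cat <- map(gt$product, function(p) {
      names(cats)[map_lgl(cats, function(kws) {
        any(str_detect(tolower(p), fixed(tolower(kws))))
      })]
    })
    is_hit <- lengths(hit_cat) > 0L
    if (!any(is_hit)) return(NULL)
    ht <- gt[is_hit, , drop = FALSE]
    ht$categories <- hit_cat[is_hit]
    runs <- ht |>
      group_by(.data$contig_id) |>
      arrange(.data$gene_index, .by_group = TRUE) |>
      mutate(new_run = c(TRUE, diff(.data$gene_index) - 1L > rule$max_gap),
             run = cumsum(.data$new_run)) |>
      ungroup()
    out <- runs |>
      group_by(.data$contig_id, .data$run) |>
      summarise(
        genes = paste(.data$gene_id, collapse = ","),
        n_genes = n(),
        categories_hit = paste(sort(unique(unlist(.data$categories))), collapse = ","),
        span_start = min(.data$start),
        span_end = max(.data$end),
        all_required = all(names(rule$required_categories) %in% unlist(.data$categories)),
        .groups = "drop"
      ) |>
      filter(.data$all_required, .data$n_genes >= rule$min_genes)
    if (nrow(out) == 0L) return(NULL)
    out |>
      mutate(genome_id = g$genome_id, rule_id = rule$rule_id) |>
      select("genome_id", "contig_id", "rule_id", "genes", "n_genes",
             "categories_hit", "span_start", "span_end")
  })
  res <- list_rbind(compact(rows))
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(genome_id = character(), contig_id = character(),
                  rule_id = character(), genes = character(),
                  n_genes = integer(), categories_hit = character(),
                  span_start = integer(), span_end = integer()))
  }
  arrange(res, .data$genome_id, .data$contig_id, .data$span_start)
}

#' The default adhesin keyword list
#'
#' The seven domain-description keywords used to flag candidate adhesion
#' proteins in syntrophic SRB annotation.
#' @return Character vector.
#' @export
adhesin_keywords <- function() {
  c("integrin", "adhesin", "cohesin", "dockerin", "fibronectin", "PilY",
    "immunoglobulin")
}

#' Flag putative adhesins by product-description keywords
#'
#' Case-insensitive substring search of each keyword against every gene's
#' product/domain description; one row per (gene, keyword) match, so a
#' description hitting two keywords yields two rows.
#'
#' @param genomes A `genome_record` or list of them.
#' @param keywords Keyword vector; defaults to [adhesin_keywords()].
#' @return Tibble: `genome_id`, `gene_id`, `matched_keyword`, `product`.
#' @export
flag_adhesins <- function(genomes, keywords = adhesin_keywords()) {
  genomes <- as_genome_list(genomes)
  rows <- map(genomes, function(g) {
    gt <- g$genes
    per_kw <- map(keywords, function(kw) {
      hit <- str_detect(tolower(gt$product), fixed(tolower(kw)))
      if (!any(hit)) return(NULL)
      tibble(genome_id = g$genome_id, gene_id = gt$gene_id[hit],
             matched_keyword = kw, product = gt$product[hit])
    })
    list_rbind(compact(per_kw))
  })
  res <- list_rbind(compact(rows))
  if (is.null(res) || nrow(res) == 0L) {
    return(tibble(genome_id = character(), gene_id = character(),
                  matched_keyword = character(), product = character()))
  }
  arrange(res, .data$genome_id, .data$gene_id, .data$matched_keyword)
}
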