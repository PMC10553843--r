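#' Classify the evolutionary history of a trait in a clade
#'
#' The four-cell rule behind the gain/loss ledger: a trait present in both
#' the syntrophic clade and its order background was inherited vertically;
#' present in the background but not the clade, it was lost during
#' specialization; present in the clade but not the background, it was
#' horizontally acquired; present in neither, it is simply absent (no
#' ancestral signal, so never scored as a loss).
#'
#' @param clade_present,background_present Logical vectors (recycled).
#' @return Character vector over
#'   `{"vertical","loss","horizontal_gain","absent"}`.
#' @examples
#' classify_history(c(TRUE, FALSE, TRUE, FALSE), c(TRUE, TRUE, FALSE, FALSE))
#' @export
classify_history <- function(clade_present, background_present) {
  if (anyNA(clade_present) || anyNA(background_present)) {
    abort("presence flags must be TRUE/FALSE, not NA")
  }
  dplyr::case_when(
    clade_present & background_present ~ "vertical",
    !clade_present & background_present ~ "loss",
    clade_present & !background_present ~ "horizontal_gain",
    TRUE ~ "absent"
  )
}

history_verdicts <- c("vertical", "loss", "horizontal_gain", "absent")

#' Infer trait histories for every (trait, syntrophic clade) pair
#'
#' Applies [classify_history()] to the group-level presence calls of a
#' [build_trait_matrix()] result: clade presence is the fraction over all
#' members of the syntrophic clade, background presence the fraction over
#' the non-syntrophic members of the clade's order, both thresholded
#' strictly at `background_presence_frac`. Each clade must map to exactly
#' one order in the taxonomy.
#'
#' @param tm A `trait_matrix`.
#' @param taxonomy Optional taxonomy tibble (`genome_id`, `order`, `clade`,
#'   `is_syntrophic`); defaults to the one captured in `tm`.
#' @return Tibble: `trait_id`, `clade`, `order`, `clade_fraction`,
#'   `background_fraction`, `clade_present`, `background_present`,
#'   `verdict`, `adapted_flag` (NA until [flag_adaptation()] is applied).
#' @export
infer_histories <- function(tm, taxonomy = NULL) {
  stopifnot(inherits(tm, "trait_matrix"))
  taxonomy <- taxonomy %||% tm$taxonomy
  syn <- taxonomy |> filter(.data$is_syntrophic)
  if (nrow(syn) == 0L) abort("taxonomy contains no syntrophic clade")
  clade_order <- syn |> distinct(.data$clade, .data$order)
  multi <- clade_order |> count(.data$clade) |> filter(.data$n > 1L)
  if (nrow(multi)) {
    abort(paste0("clade(s) mapped to more than one order: ",
                 paste(multi$clade, collapse = ", ")))
  }

  cl <- tm$fractions |>
    filter(.data$group_kind == "clade", .data$group %in% clade_order$clade) |>
    select(trait_id = "trait_id", clade = "group",
           clade_fraction = "fraction", clade_present = "present")
  missing_clades <- setdiff(clade_order$clade, unique(cl$clade))
  if (length(missing_clades)) {
    abort(paste0("no presence fractions for clade(s): ",
                 paste(missing_clades, collapse = ", ")))
  }
  bg <- tm$fractions |>
    filter(.data$group_kind == "order_background") |>
    select(order = "group", trait_id = "trait_id",
           background_fraction = "fraction", background_present = "present")

  out <- cl |>
    left_join(clade_order, by = "clade") |>
    left_join(bg, by = c("trait_id", "order"))
  if (anyNA(out$background_present)) {
    bad <- unique(out$order[is.na(out$background_present)])
    abort(paste0("no non-syntrophic background genomes for order(s): ",
                 paste(bad, collapse = ", ")))
  }
  out |>
    mutate(verdict = classify_history(.data$clade_present, .data$background_present),
           adapted_flag = NA) |>
    select("trait_id", "clade", "order", "clade_fraction",
           "background_fraction", "clade_present", "background_present",
           "verdict", "adapted_flag") |>
    arrange(.data$trait_id, .data$clade)
}

#' Flag biochemical adaptation of a vertically inherited trait
#'
#' A vertically inherited trait may still have diverged in the syntrophic
#' clade (e.g., complexes divergent from their non-syntrophic homologs).
#' The flag compares sequence cohesion: for each clade homolog take its best
#' identity to any background homolog, and compare the mean of these
#' cross-identities with the mean pairwise identity among the background
#' homologs themselves. The trait is *adapted* iff the cross-identity falls
#' more than `identity_drop` below the background cohesion.
#'
#' @param clade_seqs,background_seqs Character vectors of homolog protein
#'   sequences from the clade and the order background (>= 1 each).
#' @param identity_drop Required identity deficit, default 0.10.
#' @param verdict History verdict of the trait; anything but `"vertical"` is
#'   an error, since adaptation is only defined on vertically inherited
#'   traits.
#' @return Logical scalar with attributes `cross_identity` and
#'   `background_identity`.
#' @export
flag_adaptation <- function(clade_seqs, background_seqs, identity_drop = 0.10,
                            verdict = "vertical") {
  if (!identical(verdict, "vertical")) {
    abort("adaptation is only defined for vertically inherited traits")
  }
  if (!length(clade_seqs) || !length(background_seqs)) {
    abort("need at least one homolog on each side")
  }
  if (length(background_seqs) == 1L) {
    warn("single background homolog: background cohesion computed on n = 1")
    bg_within <- 1.0
  } else {
    pairs <- utils::combn(seq_along(background_seqs), 2L)
    bg_within <- mean(apply(pairs, 2L, function(ij) {
      global_identity(background_seqs[[ij[1]]], background_seqs[[ij[2]]])
    }))
  }
  cross <- mean(map_dbl(clade_seqs, function(cs) {
    max(map_dbl(background_seqs, function(bs) global_identity(cs, bs)))
  }))
  out <- cross < (bg_within - identity_drop)
  attr(out, "cross_identity") <- cross
  attr(out, "background_identity") <- bg_within
  out
}

#' Heatmap of trait-history verdicts
#'
#' @param histories Tibble from [infer_histories()].
#' @return A ggplot object: traits by clades, tile fill by verdict.
#' @export
plot_trait_history <- function(histories) {
  cols <- c(vertical = "#1b9e77", loss = "#d95f02",
            horizontal_gain = "#7570b3", absent = "grey92")
  histories |>
    ggplot(aes(x = .data$clade, y = .data$trait_id, fill = .data$verdict)) +
    geom_tile(color = "white") +
    scale_fill_manual(values = cols, drop = FALSE) +
    labs(x = NULL, y = NULL, fill = "history") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
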