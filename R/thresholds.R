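#' Analysis thresholds
#'
#' One bundle of the cutoffs used across the pipeline, defaulting to the
#' working definitions of the source study: a cytochrome c is *multiheme*
#' at >= 4 CxxCH motifs; a *conduit candidate* must carry strictly more than
#' 5; a beta-barrel and a conduit-candidate cytochrome form an EET conduit
#' when at most 10 genes apart on the same contig; a trait counts as present
#' in a clade or order background when its presence fraction is strictly
#' greater than 30%; species are delineated at 95% ANI or 98.65% 16S rRNA
#' identity; trait searches use a strict 1e-30 cutoff for conduit components
#' and a loose 1e-5 cutoff otherwise.
#'
#' @param multiheme_min Minimum heme (CxxCH) count for the multiheme class.
#' @param conduit_min_exclusive Conduit candidates need heme counts strictly
#'   greater than this.
#' @param neighborhood_window Maximum gene-index distance (inclusive) between
#'   a barrel and a conduit-candidate cytochrome.
#' @param background_presence_frac Presence fraction a trait must strictly
#'   exceed to count as present at clade/order level.
#' @param ani_species_cutoff Percent ANI at or above which two genomes are
#'   conspecific.
#' @param rrna_species_cutoff Percent 16S rRNA identity at or above which two
#'   genomes are conspecific.
#' @param evalue_strict,evalue_loose Default E-value cutoffs for trait
#'   searches.
#'
#' @return A named list of class `srb_thresholds`.
#' @examples
#' default_thresholds()
#' @export
default_thresholds <- function(multiheme_min = 4L,
                               conduit_min_exclusive = 5L,
                               neighborhood_window = 10L,
                               background_presence_frac = 0.30,
                               ani_species_cutoff = 95.0,
                               rrna_species_cutoff = 98.65,
                               evalue_strict = 1e-30,
                               evalue_loose = 1e-5) {
  th <- list(
    multiheme_min = as.integer(multiheme_min),
    conduit_min_exclusive = as.integer(conduit_min_exclusive),
    neighborhood_window = as.integer(neighborhood_window),
    background_presence_frac = background_presence_frac,
    ani_species_cutoff = ani_species_cutoff,
    rrna_species_cutoff = rrna_species_cutoff,
    evalue_strict = evalue_strict,
    evalue_loose = evalue_loose
  )
  ints <- c("multiheme_min", "conduit_min_exclusive", "neighborhood_window")
  for (nm in ints) {
    if (is.na(th[[nm]]) || th[[nm]] <= 0L) {
      abort(sprintf("threshold `%s` must be a positive integer", nm))
    }
  }
  if (!(th$background_presence_frac > 0 && th$background_presence_frac < 1)) {
    abort("`background_presence_frac` must lie in (0, 1)")
  }
  for (nm in c("ani_species_cutoff", "rrna_species_cutoff")) {
    if (!(th[[nm]] > 0 && th[[nm]] <= 100)) {
      abort(sprintf("threshold `%s` must lie in (0, 100]", nm))
    }
  }
  for (nm in c("evalue_strict", "evalue_loose")) {
    if (th[[nm]] <= 0) abort(sprintf("threshold `%s` must be positive", nm))
  }
  structure(th, class = "srb_thresholds")
}

#' @export
print.srb_thresholds <- function(x, ...) {
  cat("<srb_thresholds>\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
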