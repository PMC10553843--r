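the_aln <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(the_aln$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    the_aln$BLOSUM62 <- e$BLOSUM62
  }
  the_aln$BLOSUM62
}

# standard gapped Karlin-Altschul constants for BLOSUM62 with open 11 / extend 1
ka_lambda <- 0.267
ka_K <- 0.041

#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment with affine gaps, BLOSUM62 scoring and the
#' usual gap costs (open 11, extend 1; a gap of length L costs
#' `gap_open + L * gap_extend`). This is the deterministic alignment stage
#' behind the trait presence/absence searches. When no residue pair scores
#' positively the local optimum is the empty alignment with score 0.
#'
#' @param query,target Non-empty amino-acid strings.
#' @param gap_open,gap_extend Affine gap costs (positive).
#' @param substitution_matrix Substitution matrix; default BLOSUM62.
#' @return List with `score` (numeric), `identity` (matches / alignment
#'   columns of the local alignment) and `coverage` (aligned query residues /
#'   query length).
#' @examples
#' align_local("HEAGAWGHEE", "HEAGAWGHEE")
#' @export
align_local <- function(query, target, gap_open = 11, gap_extend = 1,
                        substitution_matrix = NULL) {
  stopifnot(is.character(query), is.character(target))
  if (!nchar(query) || !nchar(target)) abort("empty sequence in align_local()")
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62()
  st <- sw_stats(query, target, substitution_matrix, gap_open, gap_extend)
  if (st$score[1] <= 0) {
    return(list(score = 0, identity = 0, coverage = 0))
  }
  list(score = st$score[1],
       identity = st$nmatch[1] / st$columns[1],
       coverage = st$q_aligned[1] / nchar(query))
}

# vectorised local scores of many targets against one query
local_scores <- function(query, targets, gap_open = 11, gap_extend = 1) {
  if (!length(targets)) return(numeric())
  sw_scores(query, unname(targets), blosum62(), gap_open, gap_extend)
}

# vectorised identity / coverage stats of many targets against one query
local_stats <- function(query, targets, gap_open = 11, gap_extend = 1) {
  sw_stats(query, unname(targets), blosum62(), gap_open, gap_extend)
}

#' Karlin-Altschul E-value for a local alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with the standard gapped BLOSUM62
#' constants (lambda = 0.267, K = 0.041). E is monotone decreasing in the
#' score and linear in the search-space size `m * n`; `n` is conventionally
#' the total residue count of the searched proteome.
#'
#' @param score Local alignment score(s).
#' @param m Query length (residues).
#' @param n Database length (total residues searched).
#' @param lambda,K Karlin-Altschul parameters.
#' @return Numeric E-value(s).
#' @examples
#' estimate_evalue(60, m = 300, n = 1e5)
#' @export
estimate_evalue <- function(score, m, n, lambda = ka_lambda, K = ka_K) {
  if (any(m <= 0) || any(n <= 0)) abort("sequence lengths must be positive")
  K * m * n * exp(-lambda * score)
}

#' Bit score of a raw local alignment score
#' @inheritParams estimate_evalue
#' @return Normalised score in bits.
#' @export
bit_score <- function(score, lambda = ka_lambda, K = ka_K) {
  (lambda * score - log(K)) / log(2)
}

# Robinson & Robinson amino-acid background frequencies: the null
# composition the Karlin-Altschul constants are calibrated against.
aa_background <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441
)

#' Random protein sequences
#'
#' `composition = "natural"` draws residues from the Robinson-Robinson
#' background frequencies (the null model under which the E-value constants
#' are calibrated). `composition = "heme_free"` draws uniformly from the 18
#' standard residues excluding C and H, so generated background sequences can
#' never contain a spurious CxxCH motif — the clean-truth mode of the
#' simulator.
#'
#' @param length Sequence length(s); recycled against `n`.
#' @param n Number of sequences.
#' @param composition `"natural"` or `"heme_free"`.
#' @return Character vector of sequences.
#' @export
random_protein <- function(length, n = 1L, composition = c("natural", "heme_free")) {
  composition <- match.arg(composition)
  length <- rep_len(as.integer(length), n)
  if (composition == "natural") {
    letters_ <- names(aa_background)
    probs <- aa_background
  } else {
    letters_ <- setdiff(names(aa_background), c("C", "H"))
    probs <- rep(1 / 18, 18)
  }
  vapply(length, function(L) {
    paste(sample(letters_, L, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}
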