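# Independent oracles, kept deliberately naive: they re-derive expected
# values by brute force and must never share code with the implementation.

# motif oracle: test every 5-residue window explicitly
oracle_count_motifs <- function(seq) {
  n <- nchar(seq)
  if (n < 5L) return(list(heme_count = 0L, motif_positions = integer()))
  pos <- integer()
  for (i in seq_len(n - 4L)) {
    w <- substr(seq, i, i + 4L)
    if (substr(w, 1L, 1L) == "C" && substr(w, 4L, 4L) == "C" &&
        substr(w, 5L, 5L) == "H") {
      pos <- c(pos, i)
    }
  }
  list(heme_count = length(pos), motif_positions = pos)
}

# exhaustive affine-gap Smith-Waterman; gap of length L costs open + L * ext
oracle_local_score <- function(q, t, open = 11, ext = 1, mat = NULL) {
  if (is.null(mat)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    mat <- e$BLOSUM62
  }
  qa <- strsplit(q, "")[[1]]
  ta <- strsplit(t, "")[[1]]
  n <- length(qa); m <- length(ta)
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L) # gap in target (consumes query)
  Iy <- matrix(NEG, n + 1L, m + 1L) # gap in query (consumes target)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- mat[qa[i - 1L], ta[j - 1L]]
      M[i, j] <- max(0, M[i - 1L, j - 1L] + s, Ix[i - 1L, j - 1L] + s,
                     Iy[i - 1L, j - 1L] + s)
      Ix[i, j] <- max(M[i - 1L, j] - open - ext, Ix[i - 1L, j] - ext)
      Iy[i, j] <- max(M[i, j - 1L] - open - ext, Iy[i, j - 1L] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

random_aa <- function(n, len_range = c(50L, 200L)) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(sample(len_range[1]:len_range[2], n, replace = TRUE), function(L) {
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# minimal hand-built genome: proteins placed consecutively on one contig
toy_genome <- function(proteins, genome_id = "toy", products = NULL,
                       taxonomy = list(order = "O1", clade = "C1",
                                       is_syntrophic = TRUE)) {
  n <- length(proteins)
  if (is.null(names(proteins))) names(proteins) <- sprintf("%s_g%03d", genome_id, 1:n)
  len <- 3L * nchar(proteins) + 3L
  starts <- c(1L, cumsum(len + 20L)[-n] + 1L)
  genome_record(
    genome_id,
    genes = tibble::tibble(
      gene_id = names(proteins), contig_id = "c1",
      start = starts, end = starts + len - 1L, strand = "+",
      product = products %||% rep("hypothetical protein", n)
    ),
    proteins = proteins, taxonomy = taxonomy
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
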