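test_that("motif scanning matches hand-checked and oracle-derived examples", {
  expect_identical(count_heme_motifs(""),
                   list(heme_count = 0L, motif_positions = integer()))

  ex1 <- oracle_count_motifs("MKCAACHLLCPKCHGG")
  expect_identical(ex1$motif_positions, c(3L, 10L)) # oracle agrees with hand count
  got1 <- count_heme_motifs("MKCAACHLLCPKCHGG")
  expect_identical(got1$heme_count, 2L)
  expect_identical(got1$motif_positions, c(3L, 10L))

  # overlapping motifs share the C at position 4 and are both counted
  ex2 <- oracle_count_motifs("CAACHACH")
  expect_identical(ex2$motif_positions, c(1L, 4L))
  got2 <- count_heme_motifs("CAACHACH")
  expect_identical(got2$motif_positions, c(1L, 4L))

  # X never matches the literal C or H, but may fill wildcard positions
  expect_identical(count_heme_motifs("XAACH")$heme_count, 0L)
  expect_identical(count_heme_motifs("CAACX")$heme_count, 0L)
  expect_identical(count_heme_motifs("CXXCH")$heme_count, 1L)

  expect_error(count_heme_motifs("CaaCH"), "non-alphabetic|lowercase")
  expect_error(count_heme_motifs("CA CH"), "non-alphabetic|lowercase")

  # configurable motif: CxxxCH variant
  expect_identical(count_heme_motifs("CAAACH", motif = "CxxxCH")$heme_count, 1L)
  expect_identical(count_heme_motifs("CAAACH")$heme_count, 0L)
})

test_that("motif scanner agrees with the every-window oracle on random sequences", {
  set.seed(101)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]]
  for (i in 1:200) {
    # C/H enriched so motifs actually occur
    s <- paste(sample(aa, sample(50:400, 1), replace = TRUE,
                      prob = c(rep(1, 21)) + (aa %in% c("C", "H")) * 6),
               collapse = "")
    expect_identical(count_heme_motifs(s)$motif_positions,
                     as.integer(oracle_count_motifs(s)$motif_positions))
  }
})

test_that("heme-count classification honors the inclusive-4 / strict-5 boundaries", {
  expect_identical(classify_cytochrome(0L), "none")
  expect_identical(classify_cytochrome(1L), "cytochrome")
  expect_identical(classify_cytochrome(3L), "cytochrome")
  expect_identical(classify_cytochrome(4L), "multiheme")
  expect_identical(classify_cytochrome(5L), "multiheme") # 5 is NOT a conduit candidate
  expect_identical(classify_cytochrome(6L), "conduit_candidate")
  expect_error(classify_cytochrome(-1L), "non-negative")

  # monotone in heme count
  cats <- factor(classify_cytochrome(0:20),
                 levels = c("none", "cytochrome", "multiheme", "conduit_candidate"),
                 ordered = TRUE)
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("genome scanning returns one ordered call per motif-bearing protein", {
  g0 <- toy_genome(c(a = "MKLVDE", b = "MNPQRS")) # no cysteines at all
  expect_identical(nrow(scan_cytochromes(g0)), 0L)

  g <- toy_genome(c(
    p2 = build_cytochrome(2, 80, seed = 1),
    p4 = build_cytochrome(4, 120, seed = 2),
    p7 = build_cytochrome(7, 200, seed = 3),
    bg = random_protein(90, composition = "heme_free")
  ))
  calls <- scan_cytochromes(g)
  expect_identical(calls$gene_id, c("p2", "p4", "p7"))
  expect_identical(calls$heme_count, c(2L, 4L, 7L))
  expect_identical(calls$category, c("cytochrome", "multiheme", "conduit_candidate"))
  # motif positions round-trip through the comma-joined column
  pos <- as.integer(strsplit(calls$motif_positions[3], ",")[[1]])
  expect_identical(pos, count_heme_motifs(g$proteins[["p7"]])$motif_positions)
})

test_that("greedy type clustering separates planted families and ignores input order", {
  set.seed(7)
  famA <- random_protein(220, composition = "natural")
  famB <- random_protein(180, composition = "natural")
  seqs <- c(
    setNames(vapply(1:5, function(i) mutate_sequence(famA, 0.08), ""), paste0("a", 1:5)),
    setNames(vapply(1:5, function(i) mutate_sequence(famB, 0.08), ""), paste0("b", 1:5))
  )
  g <- toy_genome(seqs)
  calls <- tibble::tibble(genome_id = "toy", gene_id = names(seqs),
                          localization = NA_character_)
  cl <- cluster_cytochrome_types(calls, g$proteins, identity_cutoff = 0.5)
  expect_identical(length(unique(cl$type_id)), 2L)
  grp <- split(cl$gene_id, cl$type_id)
  expect_true(all(vapply(grp, function(ids) {
    length(unique(substr(ids, 1, 1))) == 1L
  }, logical(1))))

  # permutation invariance
  perm <- sample(nrow(calls))
  cl2 <- cluster_cytochrome_types(calls[perm, ], g$proteins, identity_cutoff = 0.5)
  expect_identical(dplyr::arrange(cl, gene_id), dplyr::arrange(cl2, gene_id))

  # two identical sequences form one type; unrelated pair forms two
  two <- c(x = famA, y = famA)
  cl3 <- cluster_cytochrome_types(tibble::tibble(genome_id = "t", gene_id = c("x", "y"),
                                                 localization = NA_character_),
                                  two, identity_cutoff = 0.5)
  expect_identical(length(unique(cl3$type_id)), 1L)
  unrel <- c(x = random_protein(200), y = random_protein(200))
  # independent check that the pair is below the cutoff under the clustering
  # metric (global-alignment matches / columns)
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(unrel[["x"]]), Biostrings::AAString(unrel[["y"]]),
    type = "global", substitutionMatrix = e$BLOSUM62,
    gapOpening = 11, gapExtension = 1)
  gid <- Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
  expect_lt(gid, 0.5)
  cl4 <- cluster_cytochrome_types(tibble::tibble(genome_id = "t", gene_id = c("x", "y"),
                                                 localization = NA_character_),
                                  unrel, identity_cutoff = 0.5)
  expect_identical(length(unique(cl4$type_id)), 2L)
})

test_that("type role classes follow the representative's localization label", {
  seqs <- c(e1 = build_cytochrome(6, 150, seed = 1),
            p1 = build_cytochrome(4, 100, seed = 2))
  calls <- tibble::tibble(genome_id = "t", gene_id = c("e1", "p1"),
                          localization = c("extracellular", "periplasmic"))
  cl <- cluster_cytochrome_types(calls, seqs, identity_cutoff = 0.5)
  roles <- setNames(cl$role_class, cl$gene_id)
  expect_identical(unname(roles["e1"]), "EET")
  expect_identical(unname(roles["p1"]), "periplasmic_carrier")
})
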