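# genome with a barrel and one cytochrome separated by `dist` genes
pair_genome <- function(dist, heme = 6L, n_genes = 40L, barrel_at = 5L,
                        two_contigs = FALSE) {
  prots <- setNames(random_protein(rep(60L, n_genes), n = n_genes,
                                   composition = "heme_free"),
                    sprintf("g%03d", seq_len(n_genes)))
  prots[[barrel_at + 1L]] <- build_barrel_protein(320, seed = 1)
  prots[[barrel_at + dist + 1L]] <- build_cytochrome(heme, 200, seed = 2)
  g <- toy_genome(prots, genome_id = "pg")
  if (two_contigs) {
    gt <- genes(g)
    gt$contig_id[gt$gene_id == sprintf("g%03d", barrel_at + dist + 1L)] <- "c2"
    g <- genome_record("pg", gt[c("gene_id", "contig_id", "start", "end",
                                  "strand", "product")],
                       g$proteins, taxonomy = g$taxonomy)
  }
  list(genome = g,
       barrels = tibble::tibble(gene_id = sprintf("g%03d", barrel_at + 1L),
                                label = "barrel", score = NA_real_))
}

test_that("conduit calling applies the inclusive 10-gene window and strict >5 heme rule", {
  set.seed(3)
  hit8 <- pair_genome(dist = 8L)
  out <- find_conduit_clusters(hit8$genome, scan_cytochromes(hit8$genome), hit8$barrels)
  expect_identical(nrow(out), 1L)
  expect_identical(out$min_distance, 8L)
  expect_identical(out$barrel_gene, "g006")

  # boundary: distance 10 is a hit, 11 a miss
  hit10 <- pair_genome(dist = 10L)
  expect_identical(nrow(find_conduit_clusters(hit10$genome,
                                              scan_cytochromes(hit10$genome),
                                              hit10$barrels)), 1L)
  miss11 <- pair_genome(dist = 11L)
  expect_identical(nrow(find_conduit_clusters(miss11$genome,
                                              scan_cytochromes(miss11$genome),
                                              miss11$barrels)), 0L)

  # different contigs never pair
  split_ctg <- pair_genome(dist = 3L, two_contigs = TRUE)
  expect_identical(nrow(find_conduit_clusters(split_ctg$genome,
                                              scan_cytochromes(split_ctg$genome),
                                              split_ctg$barrels)), 0L)

  # a 5-heme cytochrome adjacent to a barrel is not a conduit
  near5 <- pair_genome(dist = 1L, heme = 5L)
  expect_identical(nrow(find_conduit_clusters(near5$genome,
                                              scan_cytochromes(near5$genome),
                                              near5$barrels)), 0L)
})

test_that("clusters are barrel-anchored and reported spans cover all members", {
  set.seed(8)
  n <- 40L
  prots <- setNames(random_protein(rep(60L, n), n = n, composition = "heme_free"),
                    sprintf("g%03d", 1:n))
  prots[["g010"]] <- build_barrel_protein(320, seed = 4)
  prots[["g006"]] <- build_cytochrome(7, 200, seed = 5)
  prots[["g014"]] <- build_cytochrome(8, 200, seed = 6)
  g <- toy_genome(prots)
  barrels <- tibble::tibble(gene_id = "g010", label = "barrel", score = NA_real_)
  out <- find_conduit_clusters(g, scan_cytochromes(g), barrels)
  expect_identical(nrow(out), 1L) # one barrel -> one cluster, two cytochromes
  expect_identical(out$n_cytochromes, 2L)
  expect_identical(out$cytochrome_genes, "g006,g014")
  gt <- genes(g)
  expect_identical(out$span_start, min(gt$start[gt$gene_id %in% c("g006", "g010", "g014")]))
  expect_identical(out$span_end, max(gt$end[gt$gene_id %in% c("g006", "g010", "g014")]))
})

test_that("conduit calls are invariant to reversing contig gene order", {
  set.seed(9)
  pg <- pair_genome(dist = 7L)
  fwd <- find_conduit_clusters(pg$genome, scan_cytochromes(pg$genome), pg$barrels)
  gt <- genes(pg$genome)
  L <- max(gt$end) + 10L
  rev_gt <- gt |>
    dplyr::mutate(s = L - end, e = L - start, start = s, end = e) |>
    dplyr::select(gene_id, contig_id, start, end, strand, product)
  g_rev <- genome_record("pg", rev_gt, pg$genome$proteins, taxonomy = pg$genome$taxonomy)
  rev_out <- find_conduit_clusters(g_rev, scan_cytochromes(g_rev), pg$barrels)
  expect_identical(nrow(rev_out), 1L)
  expect_identical(rev_out$min_distance, fwd$min_distance)
  expect_identical(rev_out$barrel_gene, fwd$barrel_gene)
  expect_identical(rev_out$cytochrome_genes, fwd$cytochrome_genes)
})

test_that("reported clusters satisfy their invariants when re-checked from raw features", {
  sim <- simulate_dataset(sim_config(seed = 21, n_orders = 1L,
                                     genomes_per_order = 3L,
                                     syntrophic_clade_size = 1L,
                                     conduits = list(n_true = 3L, n_decoys = 2L,
                                                     decoy_kinds = c("far", "near_miss"),
                                                     force_boundary = TRUE)))
  calls <- scan_cytochromes(sim$genomes)
  out <- find_conduit_clusters(sim$genomes, calls, sim$barrels)
  th <- default_thresholds()
  hc <- setNames(calls$heme_count, calls$gene_id)
  for (i in seq_len(nrow(out))) {
    g <- sim$genomes[[out$genome_id[i]]]
    gt <- genes(g)
    idx <- setNames(gt$gene_index, gt$gene_id)
    ctg <- setNames(gt$contig_id, gt$gene_id)
    cyts <- strsplit(out$cytochrome_genes[i], ",")[[1]]
    expect_true(all(ctg[cyts] == out$contig_id[i]))
    expect_true(all(abs(idx[cyts] - idx[out$barrel_gene[i]]) <= th$neighborhood_window))
    expect_true(all(hc[cyts] > th$conduit_min_exclusive))
  }
})

test_that("cassette matching requires all categories within the gap limit", {
  wzx_rule <- cassette_rule(
    "wzx_wzy",
    required_categories = list(
      gt = "glycosyl transferase",
      pbp = "polysaccharide biosynthesis protein",
      transport = c("flippase", "sugar transporter")
    ),
    max_gap = 2L
  )
  mk <- function(products) {
    n <- length(products)
    toy_genome(setNames(random_protein(rep(50L, n), n = n, composition = "heme_free"),
                        sprintf("g%02d", 1:n)), products = products)
  }
  set.seed(10)
  hit <- mk(c("hypothetical protein", "glycosyl transferase",
              "polysaccharide biosynthesis protein", "flippase/sugar transporter",
              "hypothetical protein"))
  res <- match_cassettes(hit, wzx_rule)
  expect_identical(nrow(res), 1L)
  expect_identical(res$n_genes, 3L)
  expect_identical(res$categories_hit, "gt,pbp,transport")

  # a lone category gene is not a cassette
  expect_identical(nrow(match_cassettes(mk(c("glycosyl transferase",
                                             rep("hypothetical protein", 4))),
                                        wzx_rule)), 0L)

  # gap boundary: max_gap+1 intervening genes breaks the run
  gap_products <- c("glycosyl transferase", rep("hypothetical protein", 3),
                    "polysaccharide biosynthesis protein", "flippase")
  expect_identical(nrow(match_cassettes(mk(gap_products), wzx_rule)), 0L)
  gap_ok <- c("glycosyl transferase", rep("hypothetical protein", 2),
              "polysaccharide biosynthesis protein", "flippase")
  expect_identical(nrow(match_cassettes(mk(gap_ok), wzx_rule)), 1L)

  expect_error(cassette_rule("bad", required_categories = list()), "at least one")
})

test_that("adhesin flagging is case-insensitive substring matching, one row per keyword", {
  set.seed(11)
  g <- toy_genome(setNames(random_protein(rep(50L, 4), n = 4, composition = "heme_free"),
                           c("g1", "g2", "g3", "g4")),
                  products = c("Fibronectin type III domain", "Histidine kinase",
                               "Cohesin/Dockerin tandem", "PilY1 pilus adhesion protein"))
  out <- flag_adhesins(g)
  expect_identical(out$gene_id, c("g1", "g3", "g3", "g4"))
  expect_identical(out$matched_keyword, c("fibronectin", "cohesin", "dockerin", "PilY"))
  expect_identical(sort(adhesin_keywords()),
                   sort(c("integrin", "adhesin", "cohesin", "dockerin",
                          "fibronectin", "PilY", "immunoglobulin")))
})

test_that("the synthetic barrel heuristic detects built barrels and not ordinary proteins", {
  set.seed(12)
  g <- toy_genome(c(
    barrel = build_barrel_protein(320, seed = 1),
    short_barrel = build_barrel_protein(200, seed = 2), # below the length floor
    plain = random_protein(350, composition = "heme_free"),
    cyt = build_cytochrome(6, 350, seed = 3)
  ))
  pred <- predict_barrels(g)
  lab <- setNames(pred$label, pred$gene_id)
  expect_identical(unname(lab["barrel"]), "barrel")
  expect_identical(unname(lab["short_barrel"]), "not_barrel")
  expect_identical(unname(lab["plain"]), "not_barrel")
  expect_identical(unname(lab["cyt"]), "not_barrel")
})
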