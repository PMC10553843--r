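test_that("sequence mutation is deterministic, rate-faithful and alphabet-aware", {
  set.seed(71)
  dna <- random_dna(10000)
  expect_identical(mutate_sequence(dna, 0), dna)
  expect_identical(mutate_sequence(dna, 0.05, seed = 5),
                   mutate_sequence(dna, 0.05, seed = 5))
  expect_false(identical(mutate_sequence(dna, 0.05, seed = 5),
                         mutate_sequence(dna, 0.05, seed = 6)))
  expect_error(mutate_sequence(dna, 1), "rate")

  # substitution count within 3 sigma of Binomial(n, p); never same letter
  p <- 0.05
  mut <- mutate_sequence(dna, p, seed = 7)
  diffs <- sum(strsplit(dna, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(diffs - 10000 * p), 3 * sqrt(10000 * p * (1 - p)))
  expect_true(grepl("^[ACGT]+$", mut))

  # heme-free protein stays heme-free under mutation
  prot <- random_protein(5000, composition = "heme_free")
  expect_false(grepl("[CH]", mutate_sequence(prot, 0.2, seed = 8)))
})

test_that("built cytochromes scan back to their exact planted heme count", {
  for (h in c(0L, 1L, 4L, 6L, 7L, 12L)) {
    s <- build_cytochrome(h, 400, seed = h + 1L)
    expect_identical(count_heme_motifs(s)$heme_count, h)
  }
  expect_identical(classify_cytochrome(
    count_heme_motifs(build_cytochrome(6, 200, seed = 1))$heme_count
  ), "conduit_candidate")
  expect_error(build_cytochrome(10, 45), "pack")
})

test_that("simulation is byte-identical under a fixed seed and differs across seeds", {
  cfg <- sim_config(seed = 72, n_orders = 1L, genomes_per_order = 4L,
                    syntrophic_clade_size = 1L, genes_per_genome = 120L,
                    conduits = list(n_true = 1L, n_decoys = 1L,
                                    decoy_kinds = "far", force_boundary = TRUE),
                    emit_nucleotide = TRUE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir(); d3 <- withr::local_tempdir()
  simulate_dataset(cfg, out_dir = d1)
  simulate_dataset(cfg, out_dir = d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  cfg3 <- sim_config(seed = 73, n_orders = 1L, genomes_per_order = 4L,
                     syntrophic_clade_size = 1L, genes_per_genome = 120L,
                     conduits = list(n_true = 1L, n_decoys = 1L,
                                     decoy_kinds = "far", force_boundary = TRUE),
                     emit_nucleotide = TRUE)
  simulate_dataset(cfg3, out_dir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, f1[1]))),
                         unname(tools::md5sum(file.path(d3, f1[1])))))
})

test_that("emitted files re-read into records identical to the in-memory simulation", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(sim_config(seed = 74, n_orders = 1L,
                                     genomes_per_order = 3L,
                                     syntrophic_clade_size = 1L,
                                     genes_per_genome = 120L,
                                     emit_nucleotide = TRUE,
                                     conduits = list(n_true = 1L, n_decoys = 1L,
                                                     decoy_kinds = "near_miss",
                                                     force_boundary = FALSE)),
                          out_dir = dir)
  ds <- read_dataset(dir)
  expect_identical(names(ds$genomes), names(sim$genomes))
  for (gid in names(ds$genomes)) {
    expect_identical(genes(ds$genomes[[gid]]), genes(sim$genomes[[gid]]))
    expect_identical(ds$genomes[[gid]]$proteins, sim$genomes[[gid]]$proteins)
    expect_identical(ds$genomes[[gid]]$nucleotide, sim$genomes[[gid]]$nucleotide)
    expect_identical(ds$genomes[[gid]]$rrna16s, sim$genomes[[gid]]$rrna16s)
  }
  # re-scanning the emitted files reproduces planted heme counts exactly
  calls <- scan_cytochromes(ds$genomes)
  truth <- sim$truth$planted_cytochromes
  expect_setequal(calls$gene_id, truth$gene_id)
  expect_identical(calls$heme_count[match(truth$gene_id, calls$gene_id)],
                   truth$heme_count)
  # truth JSON round-trips
  tr <- read_truth(file.path(dir, "truth.json"))
  expect_identical(sort(tr$planted_cytochromes$gene_id), sort(truth$gene_id))
})

test_that("inconsistent simulation plans are rejected before emission", {
  expect_error(sim_config(traits = list(list(trait_id = "t", history = "loss",
                                             background_freq = 0, mutation_rate = 0.1))),
               "inconsistent plan")
  expect_error(sim_config(traits = list(list(trait_id = "t", history = "absent",
                                             background_freq = 0.9, mutation_rate = 0.1))),
               "inconsistent plan")
  expect_error(sim_config(genes_per_genome = 50L), "too small")
  expect_error(sim_config(traits = list(list(trait_id = "t", history = "sideways",
                                             background_freq = 0.5, mutation_rate = 0.1))),
               "unknown trait history")
})

test_that("noisy background mode records scanner-oracle heme truth", {
  sim <- simulate_dataset(sim_config(seed = 75, n_orders = 1L,
                                     genomes_per_order = 3L,
                                     syntrophic_clade_size = 1L,
                                     genes_per_genome = 120L,
                                     protein_background = "natural",
                                     conduits = list(n_true = 1L, n_decoys = 0L,
                                                     decoy_kinds = character(),
                                                     force_boundary = FALSE)))
  calls <- scan_cytochromes(sim$genomes)
  truth <- sim$truth$planted_cytochromes
  expect_identical(unique(truth$role), "scanner_oracle")
  expect_identical(sort(calls$gene_id), sort(truth$gene_id))
  expect_identical(calls$heme_count[match(truth$gene_id, calls$gene_id)],
                   truth$heme_count)
})
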