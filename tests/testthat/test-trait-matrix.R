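test_that("trait searching finds verbatim queries and honors OR over queries", {
  set.seed(31)
  target <- random_protein(200, composition = "natural")
  g <- toy_genome(setNames(c(random_protein(c(150, 180), n = 2,
                                            composition = "natural"), target),
                           c("g1", "g2", "g3")))
  tr <- trait_definition("t", target, evalue_cutoff = 1e-30)
  res <- search_trait(tr, g)
  expect_true(res$present)
  expect_identical(res$best_hit$gene_id, "g3")
  expect_equal(res$best_hit$identity, 1.0)
  expect_equal(res$best_hit$query_coverage, 1.0)

  # OR semantics: second query matches even though the first does not
  tr2 <- trait_definition("t2", c(random_protein(200), target),
                          evalue_cutoff = 1e-30)
  expect_true(search_trait(tr2, g)$present)
})

test_that("shuffled copies of a query are not hits at the strict cutoff", {
  set.seed(32)
  q <- random_protein(250, composition = "natural")
  shuffled <- vapply(1:5, function(i) {
    paste(sample(strsplit(q, "")[[1]]), collapse = "")
  }, character(1))
  g <- toy_genome(setNames(shuffled, paste0("s", 1:5)))
  tr <- trait_definition("t", q, evalue_cutoff = 1e-30)
  expect_false(search_trait(tr, g)$present)
})

test_that("presence is monotone in the E-value cutoff", {
  set.seed(33)
  q <- random_protein(200, composition = "natural")
  g <- toy_genome(setNames(c(mutate_sequence(q, 0.25),
                             random_protein(150, n = 1)), c("a", "b")))
  cutoffs <- 10^c(-40, -30, -20, -10, -5, -2)
  present <- vapply(cutoffs, function(cv) {
    search_trait(trait_definition("t", q, evalue_cutoff = cv), g)$present
  }, logical(1))
  expect_true(all(diff(as.integer(present)) >= 0)) # loosening never flips to absent
})

test_that("group presence fractions apply the strict >30% rule at the boundary", {
  set.seed(34)
  q <- random_protein(120, composition = "heme_free")
  mk <- function(id, has, syn) {
    prots <- setNames(random_protein(c(90, 110), n = 2, composition = "heme_free"),
                      paste0(id, c("_a", "_b")))
    if (has) prots[[paste0(id, "_t")]] <- q
    toy_genome(prots, genome_id = id,
               taxonomy = list(order = "O1", clade = if (syn) "C1" else "O1_bg",
                               is_syntrophic = syn))
  }
  build_with_k_of_10 <- function(k) {
    gs <- c(
      list(mk("s1", TRUE, TRUE)), # one syntrophic genome, trait present
      purrr::map(1:10, function(i) mk(paste0("b", i), i <= k, FALSE))
    )
    build_trait_matrix(list(trait_definition("t", q)), gs)
  }
  tm3 <- build_with_k_of_10(3L) # 3/10 = 0.30 -> NOT present (strict)
  bg3 <- tm3$fractions[tm3$fractions$group_kind == "order_background", ]
  expect_equal(bg3$fraction, 0.3)
  expect_false(bg3$present)

  tm4 <- build_with_k_of_10(4L) # 4/10 = 0.40 -> present
  bg4 <- tm4$fractions[tm4$fractions$group_kind == "order_background", ]
  expect_equal(bg4$fraction, 0.4)
  expect_true(bg4$present)

  # 0/10 is absent and the clade fraction counts all clade members
  tm0 <- build_with_k_of_10(0L)
  bg0 <- tm0$fractions[tm0$fractions$group_kind == "order_background", ]
  expect_equal(bg0$fraction, 0)
  cl <- tm0$fractions[tm0$fractions$group_kind == "clade" &
                        tm0$fractions$group == "C1", ]
  expect_equal(cl$fraction, 1)
})

test_that("fractions recomputed from tidy() reproduce the matrix aggregation", {
  sim <- simulate_dataset(sim_config(seed = 35, genes_per_genome = 120L,
                                     conduits = list(n_true = 1L, n_decoys = 1L,
                                                     decoy_kinds = "far",
                                                     force_boundary = FALSE)))
  tm <- build_trait_matrix(truth_trait_definitions(sim$truth), sim$genomes)
  td <- tidy(tm)
  manual <- td |>
    dplyr::filter(!is_syntrophic) |>
    dplyr::group_by(trait_id, order) |>
    dplyr::summarise(fraction = mean(present), .groups = "drop")
  stored <- tm$fractions |>
    dplyr::filter(group_kind == "order_background") |>
    dplyr::select(trait_id, order = group, fraction)
  expect_equal(dplyr::arrange(manual, trait_id, order),
               dplyr::arrange(stored, trait_id, order))
  g <- glance(tm)
  expect_identical(g$n_traits, nrow(tm$presence))
  expect_s3_class(autoplot(tm), "ggplot")
})

test_that("planted traits are recovered exactly across random plant maps", {
  for (seed in c(41L, 42L, 43L)) {
    sim <- simulate_dataset(sim_config(
      seed = seed, n_orders = 2L, genomes_per_order = 5L,
      syntrophic_clade_size = 2L, genes_per_genome = 40L,
      cytochrome_plan = list(), gene_length_aa = c(60L, 120L),
      conduits = list(n_true = 0L, n_decoys = 0L, decoy_kinds = character(),
                      force_boundary = FALSE)
    ))
    tm <- build_trait_matrix(truth_trait_definitions(sim$truth), sim$genomes)
    got <- tidy(tm) |> dplyr::arrange(trait_id, genome_id)
    want <- sim$truth$trait_presence |> dplyr::arrange(trait_id, genome_id)
    expect_identical(got$present, want$present)
  }
})

test_that("trait definitions read back from a directory with manifest overrides", {
  dir <- withr::local_tempdir()
  set.seed(36)
  writeLines(c(">q1", "MKWVTFISLLLLFSSAYS"), file.path(dir, "oetI.faa"))
  writeLines(c(">q1", "MDEKTTGWRGGHVVEGLAGELEQLRARLE"), file.path(dir, "tmc.faa"))
  writeLines(c("oetI:", "  evalue_cutoff: 1.0e-30", "  min_query_coverage: 0.7"),
             file.path(dir, "traits.yaml"))
  defs <- read_trait_definitions(dir)
  ids <- vapply(defs, function(d) d$trait_id, "")
  expect_identical(sort(ids), c("oetI", "tmc"))
  oet <- defs[[which(ids == "oetI")]]
  expect_equal(oet$evalue_cutoff, 1e-30)
  expect_equal(oet$min_query_coverage, 0.7)
  expect_equal(defs[[which(ids == "tmc")]]$evalue_cutoff, 1e-5)
})
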