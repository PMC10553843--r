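# bind rows of the non-NULL elements, or return the fallback prototype
rbind_or <- function(parts, fallback) {
  out <- list_rbind(compact(parts))
  if (is.null(out) || ncol(out) == 0L) fallback else out
}

# deterministic 32-bit stream seed from (master seed, string key)
derive_seed <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(key)) h <- (h * 31 + c) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

#' Mutate a sequence by i.i.d. substitutions
#'
#' Each site is substituted with probability `rate` to a uniformly chosen
#' *different* letter of the sequence's alphabet, so the expected number of
#' changed sites is exactly `Binomial(n, rate)`. The alphabet is inferred:
#' DNA if the sequence is pure ACGT; otherwise the 18-letter C/H-free
#' amino-acid alphabet when the input carries no C or H (preserving the
#' simulator's clean heme truth), else all 20 residues.
#'
#' @param seq Sequence (character scalar).
#' @param rate Per-site substitution probability in `[0, 1)`.
#' @param seed Optional integer; when given the mutation is deterministic.
#' @param alphabet Optional explicit alphabet (character vector).
#' @return Mutated sequence.
#' @export
mutate_sequence <- function(seq, rate, seed = NULL, alphabet = NULL) {
  if (rate < 0 || rate >= 1) abort("rate must lie in [0, 1)")
  run <- function() {
    chars <- strsplit(seq, "")[[1]]
    if (is.null(alphabet)) {
      alphabet <- if (!grepl("[^ACGT]", seq)) c("A", "C", "G", "T")
        else if (!grepl("[CH]", seq)) setdiff(names(aa_background), c("C", "H"))
        else names(aa_background)
    }
    hit <- which(runif(length(chars)) < rate)
    if (length(hit)) {
      na <- length(alphabet)
      pos <- match(chars[hit], alphabet)
      k <- sample.int(na - 1L, length(hit), replace = TRUE)
      k <- ifelse(!is.na(pos) & k >= pos, k + 1L, k)
      chars[hit] <- alphabet[k]
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Construct a protein with an exact number of CxxCH motifs
#'
#' The inverse of the motif scanner: plants exactly `heme_count`
#' non-overlapping CxxCH motifs at random positions (minimum spacing 5) and
#' fills every other position, including the motif wildcards, from the
#' C/H-free alphabet, so a scan reports exactly `heme_count` and no more.
#'
#' @param heme_count Number of motifs (>= 0).
#' @param length Total protein length; must accommodate the packing
#'   (`length >= 5 * heme_count`).
#' @param seed Optional integer for deterministic output.
#' @return Amino-acid sequence.
#' @examples
#' count_heme_motifs(build_cytochrome(7, 400, seed = 1))$heme_count
#' @export
build_cytochrome <- function(heme_count, length, seed = NULL) {
  heme_count <- as.integer(heme_count)
  if (heme_count < 0L) abort("heme_count must be >= 0")
  run <- function() {
    base <- strsplit(random_protein(length, composition = "heme_free"), "")[[1]]
    if (heme_count > 0L) {
      avail <- length - 4L - 4L * (heme_count - 1L)
      if (avail < heme_count) {
        abort(sprintf("cannot pack %d CxxCH motifs into %d residues",
                      heme_count, length))
      }
      starts <- sort(sample.int(avail, heme_count)) + 4L * (seq_len(heme_count) - 1L)
      for (s in starts) {
        base[s] <- "C"
        base[s + 3L] <- "C"
        base[s + 4L] <- "H"
      }
    }
    paste(base, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Construct a synthetic outer-membrane beta-barrel protein
#'
#' Alternating hydrophobic/polar residues (the period-2 signature of
#' membrane-spanning beta-strands) with an aromatic C-terminal residue, long
#' enough to pass [predict_barrels()]; contains no C or H.
#'
#' @param length Protein length (>= 300 to be detectable).
#' @param seed Optional integer.
#' @return Amino-acid sequence.
#' @export
build_barrel_protein <- function(length = 320L, seed = NULL) {
  run <- function() {
    hydrophobic <- c("V", "I", "L", "F", "A")
    polar <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G")
    chars <- character(length)
    odd <- seq(1L, length, by = 2L)
    even <- seq(2L, length, by = 2L)
    chars[odd] <- sample(hydrophobic, base::length(odd), replace = TRUE)
    chars[even] <- sample(polar, base::length(even), replace = TRUE)
    chars[length] <- sample(c("F", "W", "Y"), 1L)
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulation configuration
#'
#' Defines the synthetic study: taxonomic structure (orders, genomes per
#' order, one syntrophic clade per order), genome size, the planted
#' cytochrome census, the planted conduit operons and decoy layouts, and the
#' planted trait histories. Background presence of a trait in an order is
#' realized as an exact count (`round(background_freq * n_background)`), so
#' planted truth never wobbles across the >30% rule by sampling noise;
#' configurations whose realized fractions contradict the requested history
#' are rejected up front.
#'
#' @param seed Master seed; every stream is derived from it.
#' @param n_orders,genomes_per_order,syntrophic_clade_size Taxonomic layout;
#'   each order contributes its first `syntrophic_clade_size` genomes to a
#'   syntrophic clade, the rest are non-syntrophic background.
#' @param genes_per_genome Genes per genome (single contig).
#' @param gene_length_aa Length range (min, max) of background proteins.
#' @param cytochrome_plan List of `list(heme_count=, count=)` standalone
#'   cytochromes planted per genome.
#' @param conduits List with `n_true`, `n_decoys`, `decoy_kinds` (subset of
#'   `"far"`, `"near_miss"`, `"no_barrel"`, cycled), and
#'   `force_boundary` (plant one distance-10 conduit and one distance-11
#'   decoy per genome when counts allow).
#' @param traits List of `list(trait_id=, history=, background_freq=,
#'   mutation_rate=)`.
#' @param trait_query_aa Length of the generated trait query proteins.
#' @param protein_background `"heme_free"` (clean heme truth) or `"natural"`
#'   (noisy mode: truth records the scanner count of the emitted proteins).
#' @param emit_nucleotide Generate contig DNA (off by default: the planted
#'   structure of this generator is protein-level, and its random contigs
#'   carry no divergence signal; use [simulate_species_genomes()] for
#'   nucleotide-level structure). Gene coordinates are laid out either way.
#' @param intergenic_bp Spacer between consecutive genes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_orders = 2L,
                       genomes_per_order = 8L,
                       syntrophic_clade_size = 3L,
                       genes_per_genome = 240L,
                       gene_length_aa = c(80L, 200L),
                       cytochrome_plan = list(list(heme_count = 2L, count = 1L),
                                              list(heme_count = 4L, count = 1L),
                                              list(heme_count = 7L, count = 1L)),
                       conduits = list(n_true = 2L, n_decoys = 2L,
                                       decoy_kinds = c("far", "near_miss", "no_barrel"),
                                       force_boundary = TRUE),
                       traits = list(
                         list(trait_id = "trait_vertical", history = "vertical",
                              background_freq = 0.6, mutation_rate = 0.10),
                         list(trait_id = "trait_loss", history = "loss",
                              background_freq = 0.6, mutation_rate = 0.10),
                         list(trait_id = "trait_hgt", history = "horizontal_gain",
                              background_freq = 0.1, mutation_rate = 0.10),
                         list(trait_id = "trait_absent", history = "absent",
                              background_freq = 0.1, mutation_rate = 0.10)),
                       trait_query_aa = 200L,
                       protein_background = c("heme_free", "natural"),
                       emit_nucleotide = FALSE,
                       intergenic_bp = 25L) {
  protein_background <- match.arg(protein_background)
  cfg <- list(seed = as.integer(seed), n_orders = as.integer(n_orders),
              genomes_per_order = as.integer(genomes_per_order),
              syntrophic_clade_size = as.integer(syntrophic_clade_size),
              genes_per_genome = as.integer(genes_per_genome),
              gene_length_aa = as.integer(gene_length_aa),
              cytochrome_plan = cytochrome_plan, conduits = conduits,
              traits = traits, trait_query_aa = as.integer(trait_query_aa),
              protein_background = protein_background,
              emit_nucleotide = isTRUE(emit_nucleotide),
              intergenic_bp = as.integer(intergenic_bp))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

# block geometry for conduit plants: plants live in the 21-slot core of a
# 45-gene block so neighborhoods of adjacent blocks can never overlap
.block_size <- 45L
.core_offset <- 12L
.core_len <- 21L

validate_sim_config <- function(cfg) {
  if (cfg$n_orders < 1L || cfg$genomes_per_order < 2L) {
    abort("need at least 1 order with 2 genomes")
  }
  if (cfg$syntrophic_clade_size < 1L ||
      cfg$syntrophic_clade_size >= cfg$genomes_per_order) {
    abort("syntrophic_clade_size must leave at least one background genome per order")
  }
  n_bg <- cfg$genomes_per_order - cfg$syntrophic_clade_size
  thr <- default_thresholds()$background_presence_frac
  for (tr in cfg$traits) {
    if (!tr$history %in% history_verdicts) {
      abort(paste0("unknown trait history: ", tr$history))
    }
    if (tr$background_freq < 0 || tr$background_freq > 1) {
      abort("background_freq must lie in [0, 1]")
    }
    if (tr$mutation_rate < 0 || tr$mutation_rate > 0.5) {
      abort("trait mutation_rate must lie in [0, 0.5]")
    }
    realized <- round(tr$background_freq * n_bg) / n_bg
    bg_present <- realized > thr
    wants_bg <- tr$history %in% c("vertical", "loss")
    if (wants_bg && !bg_present) {
      abort(sprintf(
        "inconsistent plan for trait %s: history '%s' needs background presence, but background_freq %.2f realizes %d/%d (not > %.0f%%)",
        tr$trait_id, tr$history, tr$background_freq,
        round(tr$background_freq * n_bg), n_bg, 100 * thr))
    }
    if (!wants_bg && bg_present) {
      abort(sprintf(
        "inconsistent plan for trait %s: history '%s' needs background absence, but background_freq %.2f realizes %d/%d (> %.0f%%)",
        tr$trait_id, tr$history, tr$background_freq,
        round(tr$background_freq * n_bg), n_bg, 100 * thr))
    }
  }
  n_blocks <- cfg$conduits$n_true + cfg$conduits$n_decoys
  n_extra <- sum(map_int(cfg$cytochrome_plan, ~ as.integer(.x$count))) +
    length(cfg$traits)
  need <- n_blocks * .block_size + n_extra + 5L
  if (cfg$genes_per_genome < need) {
    abort(sprintf(
      "genes_per_genome = %d is too small for %d conduit/decoy blocks plus %d planted genes (need >= %d)",
      cfg$genes_per_genome, n_blocks, n_extra, need))
  }
  invisible(cfg)
}

#' Simulate an annotated genome set with planted truth
#'
#' Generates the full synthetic study defined by a [sim_config()]: per-order
#' syntrophic clades and non-syntrophic backgrounds, background proteomes
#' free of C/H (so heme truth is exact), planted standalone cytochromes,
#' planted porin:cytochrome conduit operons with decoy layouts (too far,
#' 5-heme near-miss, barrel-less runs), planted trait genes realizing the
#' requested vertical/loss/horizontal-gain/absent histories, per-genome 16S
#' copies and optional nucleotide contigs. Every random stream is derived
#' from `(seed, stream key)`, so regeneration is byte-identical and
#' independent of evaluation order.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, [write_dataset()] emits
#'   protein/nucleotide FASTA, GFF3, taxonomy, barrel predictions, 16S FASTA
#'   and a truth JSON there.
#' @return A `sim_dataset`: list with `genomes` (named list of
#'   `genome_record`), `truth` (planted-truth tibbles), `barrels`
#'   (prediction table) and `config`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config

  orders <- sprintf("Order%02d", seq_len(cfg$n_orders))
  taxonomy <- list_rbind(imap(orders, function(ord, oi) {
    tibble(
      genome_id = sprintf("G%02d_%02d", oi, seq_len(cfg$genomes_per_order)),
      order = ord,
      clade = ifelse(seq_len(cfg$genomes_per_order) <= cfg$syntrophic_clade_size,
                     sprintf("Clade%02d", oi), paste0(ord, "_bg")),
      is_syntrophic = seq_len(cfg$genomes_per_order) <= cfg$syntrophic_clade_size
    )
  }))

  # dataset-level streams: trait queries and background presence assignment
  trait_queries <- setNames(
    map_chr(cfg$traits, function(tr) {
      withr::with_seed(derive_seed(cfg$seed, paste0("trait_query_", tr$trait_id)),
                       random_protein(cfg$trait_query_aa, composition = "heme_free"))
    }),
    map_chr(cfg$traits, "trait_id")
  )

  empty_presence <- tibble(trait_id = character(), genome_id = character(),
                           present = logical())
  presence <- if (!length(cfg$traits)) empty_presence else
    list_rbind(map(cfg$traits, function(tr) {
    withr::with_seed(derive_seed(cfg$seed, paste0("trait_assign_", tr$trait_id)), {
      list_rbind(map(orders, function(ord) {
        memb <- taxonomy[taxonomy$order == ord, ]
        bg <- memb$genome_id[!memb$is_syntrophic]
        cl <- memb$genome_id[memb$is_syntrophic]
        n_present <- round(tr$background_freq * length(bg))
        bg_chosen <- if (n_present > 0L) sort(sample(bg, n_present)) else character()
        clade_has <- tr$history %in% c("vertical", "horizontal_gain")
        tibble(trait_id = tr$trait_id,
               genome_id = memb$genome_id,
               present = memb$genome_id %in% bg_chosen |
                 (memb$is_syntrophic & clade_has))
      }))
    })
  }))

  rrna_root <- withr::with_seed(derive_seed(cfg$seed, "rrna_root"), {
    paste(sample(c("A", "C", "G", "T"), 1500L, replace = TRUE), collapse = "")
  })

  built <- map(seq_len(nrow(taxonomy)), function(i) {
    row <- taxonomy[i, ]
    plants <- presence[presence$genome_id == row$genome_id & presence$present, ]
    build_sim_genome(cfg, row, plants, trait_queries, rrna_root)
  })
  genomes <- setNames(map(built, "genome"), taxonomy$genome_id)

  truth <- structure(list(
    taxonomy = taxonomy,
    planted_cytochromes = list_rbind(compact(map(built, "cytochromes"))),
    planted_conduits = list_rbind(compact(map(built, "conduits"))),
    planted_decoys = list_rbind(compact(map(built, "decoys"))),
    trait_presence = presence |>
      left_join(
        rbind_or(map(built, "trait_genes"),
                 tibble(trait_id = character(), genome_id = character(),
                        gene_id = character())),
        by = c("trait_id", "genome_id")),
    trait_history = rbind_or(map(cfg$traits, function(tr) {
      syn <- taxonomy[taxonomy$is_syntrophic, ]
      distinct(tibble(trait_id = tr$trait_id, clade = syn$clade,
                      order = syn$order, verdict = tr$history))
    }), tibble(trait_id = character(), clade = character(),
               order = character(), verdict = character())),
    trait_queries = trait_queries,
    species_map = NULL
  ), class = "sim_truth")

  if (cfg$protein_background == "natural") {
    # noisy mode: heme truth is whatever the scanner finds in the emission
    truth$planted_cytochromes <- scan_cytochromes(genomes) |>
      select("genome_id", "gene_id", "heme_count") |>
      mutate(role = "scanner_oracle")
  }

  barrels <- list_rbind(compact(map(built, "barrels")))
  if (is.null(barrels) || nrow(barrels) == 0L) {
    barrels <- tibble(gene_id = character(), label = character(), score = double())
  }
  attr(barrels, "kind") <- "beta_barrel"

  sim <- structure(list(genomes = genomes, truth = truth, barrels = barrels,
                        config = cfg), class = "sim_dataset")
  if (!is.null(out_dir)) write_dataset(sim, out_dir)
  sim
}

# one genome: background proteome + planted blocks, cytochromes and traits
build_sim_genome <- function(cfg, tax_row, plants, trait_queries, rrna_root) {
  gid <- tax_row$genome_id
  withr::with_seed(derive_seed(cfg$seed, gid), {
    n <- cfg$genes_per_genome
    aa_len <- sample(cfg$gene_length_aa[1]:cfg$gene_length_aa[2], n, replace = TRUE)
    comp <- if (cfg$protein_background == "natural") "natural" else "heme_free"
    prots <- random_protein(aa_len, n = n, composition = comp)
    gene_ids <- sprintf("%s_g%04d", gid, seq_len(n))
    names(prots) <- gene_ids
    product <- rep("hypothetical protein", n)

    cyt_rows <- list(); conduit_rows <- list(); decoy_rows <- list()
    barrel_rows <- list(); trait_rows <- list()

    # conduit / decoy blocks
    n_true <- cfg$conduits$n_true
    n_decoys <- cfg$conduits$n_decoys
    kinds <- rep_len(cfg$conduits$decoy_kinds, max(n_decoys, 1L))[seq_len(n_decoys)]
    blocks <- c(rep("true", n_true), kinds)
    force_b <- isTRUE(cfg$conduits$force_boundary)
    true_seen <- 0L; far_seen <- 0L
    for (b in seq_along(blocks)) {
      b0 <- (b - 1L) * .block_size # 0-based slot offset of the block
      core0 <- b0 + .core_offset
      kind <- blocks[[b]]
      if (kind == "true") {
        true_seen <- true_seen + 1L
        d <- if (force_b && true_seen == 1L) 10L else sample(1:10, 1L)
        p_b <- core0 + sample.int(.core_len - d, 1L) - 1L
        p_c <- p_b + d
        heme <- sample(6:9, 1L)
        prots[[p_b + 1L]] <- build_barrel_protein(320L)
        prots[[p_c + 1L]] <- build_cytochrome(heme, sample(250:400, 1L))
        product[[p_b + 1L]] <- "outer membrane beta-barrel porin"
        product[[p_c + 1L]] <- "multiheme c-type cytochrome"
        barrel_rows[[length(barrel_rows) + 1L]] <-
          tibble(gene_id = gene_ids[[p_b + 1L]], label = "barrel", score = 0.95)
        cyt_rows[[length(cyt_rows) + 1L]] <-
          tibble(genome_id = gid, gene_id = gene_ids[[p_c + 1L]],
                 heme_count = heme, role = "conduit")
        conduit_rows[[length(conduit_rows) + 1L]] <-
          tibble(genome_id = gid, barrel_gene = gene_ids[[p_b + 1L]],
                 cytochrome_genes = gene_ids[[p_c + 1L]], distance = d)
      } else if (kind == "far") {
        far_seen <- far_seen + 1L
        d <- if (force_b && far_seen == 1L) 11L else sample(11:20, 1L)
        p_b <- core0 + sample.int(.core_len - d, 1L) - 1L
        p_c <- p_b + d
        heme <- sample(6:9, 1L)
        prots[[p_b + 1L]] <- build_barrel_protein(320L)
        prots[[p_c + 1L]] <- build_cytochrome(heme, sample(250:400, 1L))
        product[[p_b + 1L]] <- "outer membrane beta-barrel porin"
        product[[p_c + 1L]] <- "multiheme c-type cytochrome"
        barrel_rows[[length(barrel_rows) + 1L]] <-
          tibble(gene_id = gene_ids[[p_b + 1L]], label = "barrel", score = 0.95)
        cyt_rows[[length(cyt_rows) + 1L]] <-
          tibble(genome_id = gid, gene_id = gene_ids[[p_c + 1L]],
                 heme_count = heme, role = "decoy_far")
        decoy_rows[[length(decoy_rows) + 1L]] <-
          tibble(genome_id = gid, kind = "far",
                 genes = paste(gene_ids[c(p_b, p_c) + 1L], collapse = ","),
                 distance = d)
      } else if (kind == "near_miss") {
        d <- sample(1:3, 1L)
        p_b <- core0 + sample.int(.core_len - d, 1L) - 1L
        p_c <- p_b + d
        prots[[p_b + 1L]] <- build_barrel_protein(320L)
        prots[[p_c + 1L]] <- build_cytochrome(5L, sample(250:400, 1L))
        product[[p_b + 1L]] <- "outer membrane beta-barrel porin"
        product[[p_c + 1L]] <- "pentaheme c-type cytochrome"
        barrel_rows[[length(barrel_rows) + 1L]] <-
          tibble(gene_id = gene_ids[[p_b + 1L]], label = "barrel", score = 0.95)
        cyt_rows[[length(cyt_rows) + 1L]] <-
          tibble(genome_id = gid, gene_id = gene_ids[[p_c + 1L]],
                 heme_count = 5L, role = "decoy_near_miss")
        decoy_rows[[length(decoy_rows) + 1L]] <-
          tibble(genome_id = gid, kind = "near_miss",
                 genes = paste(gene_ids[c(p_b, p_c) + 1L], collapse = ","),
                 distance = d)
      } else { # no_barrel: a run of conduit-candidate cytochromes, no porin
        p1 <- core0 + 8L
        p2 <- p1 + 2L
        h1 <- sample(6:9, 1L); h2 <- sample(6:9, 1L)
        prots[[p1 + 1L]] <- build_cytochrome(h1, sample(250:400, 1L))
        prots[[p2 + 1L]] <- build_cytochrome(h2, sample(250:400, 1L))
        product[c(p1, p2) + 1L] <- "multiheme c-type cytochrome"
        cyt_rows[[length(cyt_rows) + 1L]] <-
          tibble(genome_id = gid, gene_id = gene_ids[c(p1, p2) + 1L],
                 heme_count = c(h1, h2), role = "decoy_no_barrel")
        decoy_rows[[length(decoy_rows) + 1L]] <-
          tibble(genome_id = gid, kind = "no_barrel",
                 genes = paste(gene_ids[c(p1, p2) + 1L], collapse = ","),
                 distance = NA_integer_)
      }
    }

    # free slots after the block region for standalone cytochromes + traits
    free0 <- length(blocks) * .block_size + 1L
    free <- sample(free0:n) # random order, drawn from this genome's stream
    take <- function(k) {
      got <- free[seq_len(k)]
      free <<- free[-seq_len(k)]
      got
    }
    for (pl in cfg$cytochrome_plan) {
      for (ct in seq_len(pl$count)) {
        slot <- take(1L)
        prots[[slot]] <- build_cytochrome(pl$heme_count,
                                          sample(150:400, 1L))
        product[[slot]] <- "c-type cytochrome"
        cyt_rows[[length(cyt_rows) + 1L]] <-
          tibble(genome_id = gid, gene_id = gene_ids[[slot]],
                 heme_count = as.integer(pl$heme_count), role = "standalone")
      }
    }
    for (tid in plants$trait_id) {
      tr <- keep(cfg$traits, ~ .x$trait_id == tid)[[1]]
      slot <- take(1L)
      prots[[slot]] <- mutate_sequence(trait_queries[[tid]], tr$mutation_rate)
      product[[slot]] <- paste0("trait protein ", tid)
      trait_rows[[length(trait_rows) + 1L]] <-
        tibble(trait_id = tid, genome_id = gid, gene_id = gene_ids[[slot]])
    }

    # coordinates (and contig DNA when requested)
    nt_len <- 3L * nchar(prots) + 3L
    starts <- cfg$intergenic_bp + c(0L, cumsum(nt_len + cfg$intergenic_bp))[seq_len(n)] + 1L
    ends <- starts + nt_len - 1L
    contig_len <- ends[n] + cfg$intergenic_bp
    nuc <- NULL
    if (cfg$emit_nucleotide) {
      nuc <- setNames(
        paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
              collapse = ""),
        paste0(gid, "_c1"))
    }
    rrna <- mutate_sequence(rrna_root, 0.01)

    genome <- genome_record(
      gid,
      genes = tibble(gene_id = gene_ids, contig_id = paste0(gid, "_c1"),
                     start = starts, end = ends,
                     strand = sample(c("+", "-"), n, replace = TRUE),
                     product = product),
      proteins = prots, nucleotide = nuc, rrna16s = rrna,
      taxonomy = list(order = tax_row$order, clade = tax_row$clade,
                      is_syntrophic = tax_row$is_syntrophic)
    )
    list(genome = genome,
         cytochromes = list_rbind(compact(cyt_rows)),
         conduits = list_rbind(compact(conduit_rows)),
         decoys = list_rbind(compact(decoy_rows)),
         barrels = list_rbind(compact(barrel_rows)),
         trait_genes = list_rbind(compact(trait_rows)))
  })
}

#' Trait definitions matching a simulation's planted queries
#'
#' @param truth A `sim_truth` (from [simulate_dataset()]).
#' @param evalue_cutoff,min_query_coverage Search thresholds.
#' @return List of [trait_definition()] objects.
#' @export
truth_trait_definitions <- function(truth,
                                    evalue_cutoff = default_thresholds()$evalue_loose,
                                    min_query_coverage = 0.5) {
  imap(as.list(truth$trait_queries), function(q, tid) {
    trait_definition(tid, q, evalue_cutoff = evalue_cutoff,
                     min_query_coverage = min_query_coverage)
  }) |> unname()
}

#' Simulate genome sets with planted species structure
#'
#' Nucleotide-level simulation for ANI/16S species delineation: one root
#' genome, per-species ancestors diverged so that the expected *pairwise*
#' divergence between species equals `between_divergence`, and members
#' diverged within species to pairwise `within_divergence`. Requested
#' divergences are converted to per-copy substitution rates by inverting the
#' two-branch relation `d = 2q(1-q) + (2/3)q^2`. Each genome also carries a
#' 16S copy with its own within/between divergences.
#'
#' @param n_species,genomes_per_species Species layout.
#' @param genome_length Genome length in bp (single contig).
#' @param within_divergence,between_divergence Pairwise nucleotide
#'   divergence targets (e.g. 0.01 -> ANI ~ 99).
#' @param rrna_within,rrna_between Pairwise divergence targets for the 16S
#'   copies.
#' @param rrna_length 16S length in bp.
#' @param seed Master seed.
#' @return List with `genomes` (named list of `genome_record`) and `truth`
#'   (tibble `genome_id`, `species_id`).
#' @export
simulate_species_genomes <- function(n_species = 3L, genomes_per_species = 3L,
                                     genome_length = 20000L,
                                     within_divergence = 0.01,
                                     between_divergence = 0.12,
                                     rrna_within = 0.005, rrna_between = 0.05,
                                     rrna_length = 1500L, seed = 1L) {
  q_b <- divergence_to_rate(between_divergence)
  q_w <- divergence_to_rate(within_divergence)
  q16_b <- divergence_to_rate(rrna_between)
  q16_w <- divergence_to_rate(rrna_within)

  root <- withr::with_seed(derive_seed(seed, "species_root"), {
    paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE), collapse = "")
  })
  root16 <- withr::with_seed(derive_seed(seed, "species_root16"), {
    paste(sample(c("A", "C", "G", "T"), rrna_length, replace = TRUE), collapse = "")
  })

  genomes <- list()
  rows <- list()
  for (s in seq_len(n_species)) {
    anc <- mutate_sequence(root, q_b, seed = derive_seed(seed, paste0("anc_", s)))
    anc16 <- mutate_sequence(root16, q16_b, seed = derive_seed(seed, paste0("anc16_", s)))
    for (g in seq_len(genomes_per_species)) {
      gid <- sprintf("sp%02d_g%02d", s, g)
      nuc <- mutate_sequence(anc, q_w, seed = derive_seed(seed, paste0("nuc_", gid)))
      r16 <- mutate_sequence(anc16, q16_w, seed = derive_seed(seed, paste0("16s_", gid)))
      genomes[[gid]] <- genome_record(
        gid,
        genes = tibble(gene_id = character(), contig_id = character(),
                       start = integer(), end = integer(), strand = character()),
        proteins = setNames(character(), character()),
        nucleotide = setNames(nuc, paste0(gid, "_c1")),
        rrna16s = r16,
        taxonomy = list(order = "SimOrder", clade = sprintf("sp%02d", s),
                        is_syntrophic = FALSE)
      )
      rows[[length(rows) + 1L]] <- tibble(genome_id = gid,
                                          species_id = sprintf("sp%02d", s))
    }
  }
  list(genomes = genomes, truth = list_rbind(rows))
}

# invert pairwise divergence d = 2q(1-q) + (2/3)q^2 for the per-copy rate q
divergence_to_rate <- function(d) {
  if (d < 0 || d >= 0.75) abort("divergence must lie in [0, 0.75)")
  if (d == 0) return(0)
  (2 - sqrt(4 - (16 / 3) * d)) / (8 / 3)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d genomes, %d planted cytochromes, %d conduits, %d decoys, %d traits\n",
              length(x$genomes),
              nrow(x$truth$planted_cytochromes %||% tibble()),
              nrow(x$truth$planted_conduits %||% tibble()),
              nrow(x$truth$planted_decoys %||% tibble()),
              length(x$truth$trait_queries)))
  invisible(x)
}
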