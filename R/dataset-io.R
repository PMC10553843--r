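#' Write a simulated dataset to disk
#'
#' Emits the directory layout the pipeline consumes: per genome
#' `<id>.faa`, `<id>.gff` (and `<id>.fna` when nucleotide contigs exist),
#' plus `taxonomy.tsv`, `barrels.tsv` (planted beta-barrel predictions),
#' `rrna_16s.fna` and `truth.json`.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes) {
    write_fasta(g$proteins, file.path(dir, paste0(g$genome_id, ".faa")))
    write_gff3(g, file.path(dir, paste0(g$genome_id, ".gff")))
    if (!is.null(g$nucleotide)) {
      write_fasta(g$nucleotide, file.path(dir, paste0(g$genome_id, ".fna")))
    }
  }
  readr::write_tsv(sim$truth$taxonomy, file.path(dir, "taxonomy.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$barrels, file.path(dir, "barrels.tsv"), progress = FALSE)
  rrna <- compact(map(sim$genomes, "rrna16s"))
  if (length(rrna)) {
    write_fasta(unlist(rrna), file.path(dir, "rrna_16s.fna"))
  }
  truth <- sim$truth
  truth$trait_queries <- as.list(truth$trait_queries)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "wb") # binary mode: LF on every platform
  on.exit(close(con))
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(c(paste0(">", nm), substring(s, starts, starts + width - 1L)),
               con, sep = "\n")
  }
  invisible(path)
}

write_gff3 <- function(genome, path) {
  gt <- genome$genes
  lines <- c("##gff-version 3",
             sprintf("%s\tsyntrophr\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                     gt$contig_id, gt$start, gt$end, gt$strand, gt$gene_id,
                     gsub("[;=,\t]", " ", gt$product)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a dataset directory into genome records
#'
#' Inverse of [write_dataset()] (minus the truth file): reads
#' `taxonomy.tsv`, one `<genome_id>.faa` + `<genome_id>.gff` (+ optional
#' `.fna`) per taxonomy row, and 16S copies from `rrna_16s.fna` when
#' present.
#'
#' @param dir Dataset directory.
#' @return List with `genomes` (named list of `genome_record`), `taxonomy`
#'   (tibble) and `barrels` (prediction table or NULL).
#' @export
read_dataset <- function(dir) {
  tax_path <- file.path(dir, "taxonomy.tsv")
  if (!file.exists(tax_path)) abort(paste0("no such file: ", tax_path))
  taxonomy <- read_taxonomy(tax_path)
  rrna <- NULL
  rrna_path <- file.path(dir, "rrna_16s.fna")
  if (file.exists(rrna_path)) {
    rr <- Biostrings::readDNAStringSet(rrna_path)
    rrna <- setNames(as.character(rr), sub("\\s.*$", "", names(rr)))
  }
  genomes <- map(seq_len(nrow(taxonomy)), function(i) {
    row <- taxonomy[i, ]
    fna <- file.path(dir, paste0(row$genome_id, ".fna"))
    read_genome(
      protein_fasta = file.path(dir, paste0(row$genome_id, ".faa")),
      gff = file.path(dir, paste0(row$genome_id, ".gff")),
      taxonomy_row = row, genome_id = row$genome_id,
      nucleotide_fasta = if (file.exists(fna)) fna else NULL,
      rrna16s = if (!is.null(rrna)) rrna[[row$genome_id]] else NULL
    )
  })
  names(genomes) <- taxonomy$genome_id
  barrels <- NULL
  bpath <- file.path(dir, "barrels.tsv")
  if (file.exists(bpath)) barrels <- read_prediction_table(bpath, "beta_barrel")
  list(genomes = genomes, taxonomy = taxonomy, barrels = barrels)
}

#' Read a simulation truth file
#'
#' @param path Path to `truth.json`.
#' @return A `sim_truth`-like list of tibbles.
#' @export
read_truth <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  for (nm in c("taxonomy", "planted_cytochromes", "planted_conduits",
               "planted_decoys", "trait_presence", "trait_history")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- as_tibble(raw[[nm]])
  }
  if (!is.null(raw$trait_queries)) raw$trait_queries <- unlist(raw$trait_queries)
  structure(raw, class = "sim_truth")
}
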