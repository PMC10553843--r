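#' Assemble a genome record
#'
#' The in-memory unit of the pipeline: one annotated genome (typically a MAG)
#' with its ordered gene features, protein sequences, optional nucleotide
#' contigs and 16S sequence, and taxonomy labels. Gene order is summarised by
#' `gene_index`, the 0-based rank of each gene along its contig by ascending
#' start coordinate — the unit in which conduit neighborhood distances are
#' measured. Ties in start are broken by end, then by gene_id, so the index
#' is a pure function of the coordinates and never of input line order.
#'
#' @param genome_id Genome identifier.
#' @param genes Data frame with columns `gene_id`, `contig_id`, `start`,
#'   `end`, `strand` and optionally `product` (free-text domain/product
#'   descriptions, `;`-separated when several).
#' @param proteins Named character vector of amino-acid sequences, one per
#'   `gene_id`. Terminal stop codons (`*`) are stripped; an internal `*` is
#'   an error. Only the 20 standard residues plus `X` are allowed.
#' @param nucleotide Optional named character vector of contig DNA sequences.
#' @param rrna16s Optional 16S rRNA DNA sequence.
#' @param taxonomy List or one-row data frame with `order`, `clade`,
#'   `is_syntrophic`.
#'
#' @return An object of class `genome_record`.
#' @examples
#' g <- genome_record(
#'   "g1",
#'   genes = data.frame(
#'     gene_id = c("a", "b"), contig_id = "c1",
#'     start = c(1, 400), end = c(300, 700), strand = "+"
#'   ),
#'   proteins = c(a = "MKLV", b = "MNPQ"),
#'   taxonomy = list(order = "O1", clade = "bg", is_syntrophic = FALSE)
#' )
#' genes(g)
#' @export
genome_record <- function(genome_id, genes, proteins, nucleotide = NULL,
                          rrna16s = NULL, taxonomy = list(order = NA_character_,
                                                          clade = NA_character_,
                                                          is_syntrophic = NA)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  genes <- as_tibble(genes)
  required <- c("gene_id", "contig_id", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols)) {
    abort(paste0("`genes` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (!"product" %in% names(genes)) genes$product <- ""
  genes$product[is.na(genes$product)] <- ""
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$end < genes$start)) {
    bad <- genes$gene_id[genes$end < genes$start]
    abort(paste0("end < start for gene(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(genes$gene_id)) {
    abort(paste0("duplicate gene_id(s): ",
                 paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")

  genes <- genes |>
    arrange(.data$contig_id, .data$start, .data$end, .data$gene_id) |>
    group_by(.data$contig_id) |>
    mutate(gene_index = seq_len(n()) - 1L) |>
    ungroup() |>
    select("gene_id", "contig_id", "start", "end", "strand", "gene_index", "product")

  proteins <- clean_proteins(proteins)
  no_protein <- setdiff(genes$gene_id, names(proteins))
  if (length(no_protein)) {
    abort(paste0("no protein sequence for annotated gene(s): ",
                 paste(no_protein, collapse = ", ")))
  }
  orphan <- setdiff(names(proteins), genes$gene_id)
  if (length(orphan)) {
    abort(paste0("protein sequence(s) with no annotated feature: ",
                 paste(orphan, collapse = ", ")))
  }
  proteins <- proteins[genes$gene_id]

  if (!is.null(nucleotide)) {
    stopifnot(is.character(nucleotide), !is.null(names(nucleotide)))
    by_contig <- split(genes$end, genes$contig_id)
    for (ctg in names(by_contig)) {
      if (!ctg %in% names(nucleotide)) {
        abort(paste0("genes annotated on contig absent from nucleotide set: ", ctg))
      }
      if (max(by_contig[[ctg]]) > nchar(nucleotide[[ctg]])) {
        abort(paste0("gene coordinates exceed contig length on: ", ctg))
      }
    }
  }

  taxonomy <- as.list(taxonomy)[c("order", "clade", "is_syntrophic")]
  structure(
    list(genome_id = genome_id, genes = genes, proteins = proteins,
         nucleotide = nucleotide, rrna16s = rrna16s, taxonomy = taxonomy),
    class = "genome_record"
  )
}

# terminal '*' stripped; internal '*' or non-standard residues rejected
clean_proteins <- function(proteins) {
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  proteins <- sub("\\*+$", "", proteins)
  bad_internal <- grepl("\\*", proteins)
  if (any(bad_internal)) {
    abort(paste0("internal stop codon(s) in protein(s): ",
                 paste(names(proteins)[bad_internal], collapse = ", ")))
  }
  bad_alpha <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", proteins)
  if (any(bad_alpha)) {
    abort(paste0("non-standard residues in protein(s): ",
                 paste(names(proteins)[bad_alpha], collapse = ", ")))
  }
  proteins
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d genes on %d contig(s)%s\n",
              x$genome_id, nrow(x$genes), length(unique(x$genes$contig_id)),
              if (is.null(x$nucleotide)) "" else sprintf(", %d bp",
                sum(nchar(x$nucleotide)))))
  cat(sprintf("  taxonomy: order=%s clade=%s syntrophic=%s\n",
              x$taxonomy$order, x$taxonomy$clade, x$taxonomy$is_syntrophic))
  invisible(x)
}

#' Gene feature table of a genome record
#' @param genome A `genome_record`.
#' @return Tibble of gene features with `gene_index`.
#' @export
genes <- function(genome) {
  stopifnot(inherits(genome, "genome_record"))
  genome$genes
}

#' Read one genome from protein FASTA + GFF3
#'
#' Parses CDS features from a GFF3 file, pairs them with protein sequences by
#' identifier, and assembles a validated [genome_record()]. FASTA identifiers
#' must match the GFF `ID` attribute of CDS features (the part before the
#' first whitespace). Every CDS must have a protein and every protein a CDS;
#' violations are errors naming the offending identifiers. Malformed GFF
#' lines (not 9 tab-separated fields) are reported with their line number.
#'
#' @param protein_fasta Path to the protein FASTA.
#' @param gff Path to the GFF3 annotation.
#' @param taxonomy_row List or one-row data frame with `order`, `clade`,
#'   `is_syntrophic` (and optionally `genome_id`).
#' @param genome_id Genome identifier; defaults to the FASTA basename.
#' @param nucleotide_fasta Optional path to the contig DNA FASTA.
#' @param rrna16s Optional 16S rRNA sequence (character).
#'
#' @return A `genome_record`.
#' @export
read_genome <- function(protein_fasta, gff, taxonomy_row,
                        genome_id = NULL, nucleotide_fasta = NULL,
                        rrna16s = NULL) {
  if (!file.exists(protein_fasta)) abort(paste0("no such file: ", protein_fasta))
  if (!file.exists(gff)) abort(paste0("no such file: ", gff))
  validate_gff_lines(gff)

  feats <- rtracklayer::import(gff, format = "gff3")
  feats <- feats[tolower(as.character(feats$type)) == "cds"]
  if (length(feats) == 0L) abort(paste0("no CDS features in ", gff))
  ids <- feats$ID
  if (is.null(ids) || anyNA(ids)) abort(paste0("CDS feature(s) without ID attribute in ", gff))
  prod <- feats$product
  if (is.null(prod)) prod <- rep("", length(feats))
  gtab <- tibble(
    gene_id = as.character(ids),
    contig_id = as.character(GenomicRanges::seqnames(feats)),
    start = GenomicRanges::start(feats),
    end = GenomicRanges::end(feats),
    strand = ifelse(as.character(GenomicRanges::strand(feats)) == "-", "-", "+"),
    product = ifelse(is.na(prod), "", as.character(prod))
  )

  aa <- Biostrings::readAAStringSet(protein_fasta)
  prot <- setNames(as.character(aa), sub("\\s.*$", "", names(aa)))

  nuc <- NULL
  if (!is.null(nucleotide_fasta)) {
    dn <- Biostrings::readDNAStringSet(nucleotide_fasta)
    nuc <- setNames(as.character(dn), sub("\\s.*$", "", names(dn)))
  }

  if (is.null(genome_id)) {
    genome_id <- taxonomy_row[["genome_id"]] %||%
      sub("\\.(faa|fa|fasta)$", "", basename(protein_fasta))
  }
  genome_record(genome_id, gtab, prot, nucleotide = nuc, rrna16s = rrna16s,
                taxonomy = taxonomy_row)
}

validate_gff_lines <- function(gff) {
  lines <- readLines(gff, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (ln == "" || startsWith(ln, "#")) next
    if (length(strsplit(ln, "\t", fixed = TRUE)[[1]]) != 9L) {
      abort(sprintf("malformed GFF line %d in %s (expected 9 tab-separated fields)", i, gff))
    }
  }
  invisible(TRUE)
}

#' Read a taxonomy table
#'
#' @param path TSV with columns `genome_id`, `order`, `clade`,
#'   `is_syntrophic` (logical or 0/1).
#' @return Tibble with those four columns.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("genome_id", "order", "clade", "is_syntrophic")
  missing_cols <- setdiff(need, names(tax))
  if (length(missing_cols)) {
    abort(paste0(path, " is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(tax$genome_id)) abort("duplicate genome_id in taxonomy table")
  tax$is_syntrophic <- as.logical(tax$is_syntrophic)
  as_tibble(tax[need])
}

pred_labels <- list(
  beta_barrel = c("barrel", "not_barrel"),
  localization = c("periplasmic", "extracellular", "cytoplasmic", "membrane", "unknown")
)

#' Read an external prediction table
#'
#' Ingests per-gene predictions from external tools consumed as flat tables:
#' outer-membrane beta-barrel calls (`kind = "beta_barrel"`, labels `barrel` /
#' `not_barrel`) or subcellular localization (`kind = "localization"`, labels
#' `periplasmic`, `extracellular`, `cytoplasmic`, `membrane`, `unknown`).
#' The label vocabulary is closed; unknown labels and duplicate gene ids are
#' errors. An empty file yields an empty table with a warning.
#'
#' @param tsv Path to a TSV with columns `gene_id`, `label` and optionally
#'   `score`.
#' @param kind `"beta_barrel"` or `"localization"`.
#' @return Tibble `gene_id`, `label`, `score` with attribute `kind`.
#' @export
read_prediction_table <- function(tsv, kind = c("beta_barrel", "localization")) {
  kind <- match.arg(kind)
  tab <- readr::read_tsv(tsv, show_col_types = FALSE, progress = FALSE)
  if (nrow(tab) == 0L) {
    warn(paste0("empty prediction table: ", tsv))
    out <- tibble(gene_id = character(), label = character(), score = double())
    attr(out, "kind") <- kind
    return(out)
  }
  if (!all(c("gene_id", "label") %in% names(tab))) {
    abort(paste0(tsv, " must have columns gene_id, label[, score]"))
  }
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  if (anyDuplicated(tab$gene_id)) {
    abort(paste0("duplicate gene_id row(s) in ", tsv, ": ",
                 paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", ")))
  }
  bad <- setdiff(unique(tab$label), pred_labels[[kind]])
  if (length(bad)) {
    abort(paste0("unknown ", kind, " label(s): ", paste(bad, collapse = ", "),
                 " (allowed: ", paste(pred_labels[[kind]], collapse = ", "), ")"))
  }
  out <- as_tibble(tab[c("gene_id", "label", "score")])
  attr(out, "kind") <- kind
  out
}

#' Write / read the package's flat annotation table
#'
#' A single TSV carrying everything needed to reconstruct a `genome_record`
#' without re-parsing FASTA/GFF: coordinates, strand, gene index, product
#' text and the protein sequence itself. `read_annotation_tsv()` is the exact
#' inverse of `write_annotation_tsv()`.
#'
#' @param genome A `genome_record`.
#' @param path Output/input TSV path.
#' @param taxonomy_row Taxonomy labels for the re-read record.
#' @return `write_annotation_tsv()` returns `path` invisibly;
#'   `read_annotation_tsv()` returns a `genome_record`.
#' @export
write_annotation_tsv <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  tab <- genome$genes |>
    mutate(genome_id = genome$genome_id,
           protein = unname(genome$proteins[.data$gene_id])) |>
    select("genome_id", "contig_id", "gene_id", "start", "end", "strand",
           "gene_index", "product", "protein")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_annotation_tsv
#' @export
read_annotation_tsv <- function(path, taxonomy_row = list(order = NA_character_,
                                                          clade = NA_character_,
                                                          is_syntrophic = NA)) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(product = readr::col_character()))
  tab$product[is.na(tab$product)] <- ""
  gid <- unique(tab$genome_id)
  if (length(gid) != 1L) abort("annotation TSV must describe exactly one genome")
  genome_record(gid, tab[c("gene_id", "contig_id", "start", "end", "strand", "product")],
                setNames(tab$protein, tab$gene_id), taxonomy = taxonomy_row)
}
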