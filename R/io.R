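# Readers/writers for on-disk formats and the quality-control filters.

#' Quality-control configuration
#'
#' Default thresholds for sample (cell) and gene filters. Cells must have at
#' least `min_mapped_reads` mapped reads, less than `max_ercc_fraction` ERCC
#' reads, at least `min_genes_detected` genes with a read, and (optionally)
#' be confirmed single cells. Genes must have a per-cell molecule count
#' below `max_molecules` in every cell (UMI saturation: 6 bp UMIs
#' distinguish at most 4^6 = 4096 molecules; set
#' `molecule_filter = "total"` to apply the bound to the per-gene total
#' instead) and median log CPM of at least `min_median_log_cpm`.
#'
#' @param min_mapped_reads minimum mapped reads per cell.
#' @param max_ercc_fraction maximum ERCC read fraction (exclusive bound).
#' @param min_genes_detected minimum genes with >= 1 read per cell.
#' @param require_single_cell drop cells not flagged as single cells.
#' @param max_molecules per-cell molecule bound per gene (exclusive).
#' @param molecule_filter `"per_cell_max"` or `"total"`.
#' @param min_median_log_cpm minimum per-gene median log CPM (inclusive).
#' @return List of thresholds.
#' @export
qc_config <- function(min_mapped_reads = 1011612,
                      max_ercc_fraction = 0.49,
                      min_genes_detected = 4730,
                      require_single_cell = TRUE,
                      max_molecules = 4096,
                      molecule_filter = c("per_cell_max", "total"),
                      min_median_log_cpm = 3) {
  stopifnot(min_mapped_reads > 0, max_ercc_fraction > 0,
            min_genes_detected > 0, max_molecules > 0)
  list(min_mapped_reads = min_mapped_reads,
       max_ercc_fraction = max_ercc_fraction,
       min_genes_detected = min_genes_detected,
       require_single_cell = isTRUE(require_single_cell),
       max_molecules = max_molecules,
       molecule_filter = match.arg(molecule_filter),
       min_median_log_cpm = min_median_log_cpm)
}

validate_bundle <- function(bundle) {
  counts <- bundle$counts
  if (any(counts < 0)) stop_input("negative counts")
  if (nrow(counts) != nrow(bundle$genes))
    stop_input("gene metadata rows (%d) do not match count matrix rows (%d)",
               nrow(bundle$genes), nrow(counts))
  if (ncol(counts) != nrow(bundle$cells))
    stop_input("cell metadata rows (%d) do not match count matrix columns (%d)",
               nrow(bundle$cells), ncol(counts))
  if (anyDuplicated(bundle$cells$cell)) stop_input("duplicate cell ids")
  if (anyDuplicated(bundle$genes$gene)) stop_input("duplicate gene ids")
  invisible(bundle)
}

#' Read a count dataset bundle from disk
#'
#' Accepts either a MatrixMarket sparse matrix (`.mtx`) with companion
#' `genes.tsv`/`cells.tsv` metadata, or a single dense TSV whose first
#' column is the gene id and whose remaining columns are cells. Dimensions
#' and id uniqueness are validated.
#'
#' @param counts_path path to `.mtx` or dense `.tsv`.
#' @param genes_path TSV with a `gene` column (required for `.mtx`).
#' @param cells_path TSV with a `cell` column plus metadata (required for
#'   `.mtx`; optional for dense TSV, where minimal metadata is synthesized
#'   from the header).
#' @return A bundle: list with `counts` (genes x cells base matrix),
#'   `cells`, `genes`.
#' @export
read_counts <- function(counts_path, genes_path = NULL, cells_path = NULL) {
  if (!file.exists(counts_path)) stop_input("no such file: %s", counts_path)
  if (grepl("\\.mtx$", counts_path)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop_input("genes_path and cells_path are required with MatrixMarket input")
    m <- tryCatch(as.matrix(Matrix::readMM(counts_path)),
                  error = function(e) stop_input("malformed MatrixMarket file: %s",
                                                 conditionMessage(e)))
    genes <- read_tsv(genes_path)
    cells <- read_tsv(cells_path)
    if (!"gene" %in% names(genes)) stop_input("genes file must have a 'gene' column")
    if (!"cell" %in% names(cells)) stop_input("cells file must have a 'cell' column")
    rownames(m) <- genes$gene
    colnames(m) <- cells$cell
  } else {
    d <- read_tsv(counts_path)
    genes <- data.frame(gene = as.character(d[[1L]]), stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1L, drop = FALSE])
    rownames(m) <- genes$gene
    cells <- if (!is.null(cells_path)) read_tsv(cells_path)
             else data.frame(cell = colnames(m), stringsAsFactors = FALSE)
    if (!is.null(genes_path)) genes <- read_tsv(genes_path)
  }
  validate_bundle(list(counts = m, cells = cells, genes = genes))
}

#' Write a count dataset bundle to disk
#'
#' @param bundle a dataset bundle (`counts`, `cells`, `genes`).
#' @param dir output directory (created if needed).
#' @param format `"mtx"` (MatrixMarket + metadata TSVs) or `"tsv"` (dense).
#' @return Invisibly, the paths written.
#' @export
write_counts <- function(bundle, dir, format = c("mtx", "tsv")) {
  format <- match.arg(format)
  validate_bundle(bundle)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "cells.tsv"))
  write_tsv_det(bundle$genes, paths["genes"])
  write_tsv_det(bundle$cells, paths["cells"])
  if (format == "mtx") {
    paths["counts"] <- file.path(dir, "counts.mtx")
    Matrix::writeMM(Matrix::Matrix(as.matrix(bundle$counts), sparse = TRUE),
                    paths["counts"])
  } else {
    paths["counts"] <- file.path(dir, "counts.tsv")
    df <- data.frame(gene = bundle$genes$gene, as.matrix(bundle$counts),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("gene", bundle$cells$cell)
    write.table(df, paths["counts"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}

#' Apply cell and gene quality-control filters
#'
#' Cell filters use metadata columns where available (`mapped_reads`,
#' `ercc_fraction`, `single_cell`); `genes_detected` is computed from the
#' counts if absent. Filters whose columns are missing are skipped with a
#' warning. Gene filters: molecule bound (per-cell max by default) and
#' median log CPM. The report lists how many cells/genes each criterion
#' removed (cells can fail several criteria).
#'
#' @param bundle a dataset bundle.
#' @param qc a [qc_config()].
#' @return List with `bundle` (filtered) and `report` (data.frame:
#'   criterion, removed).
#' @export
apply_qc <- function(bundle, qc = qc_config()) {
  validate_bundle(bundle)
  counts <- as.matrix(bundle$counts)
  cells <- bundle$cells
  keep_cell <- rep(TRUE, ncol(counts))
  report <- list()
  check <- function(name, fail) {
    report[[length(report) + 1L]] <<- data.frame(criterion = name,
                                                 removed = sum(fail))
    keep_cell <<- keep_cell & !fail
  }
  if ("mapped_reads" %in% names(cells)) {
    check("mapped_reads", cells$mapped_reads < qc$min_mapped_reads)
  } else warning("no 'mapped_reads' column; filter skipped")
  if ("ercc_fraction" %in% names(cells)) {
    check("ercc_fraction", cells$ercc_fraction >= qc$max_ercc_fraction)
  } else warning("no 'ercc_fraction' column; filter skipped")
  gd <- if ("genes_detected" %in% names(cells)) cells$genes_detected
        else colSums(counts >= 1)
  check("genes_detected", gd < qc$min_genes_detected)
  if (qc$require_single_cell) {
    if ("single_cell" %in% names(cells)) {
      check("single_cell", !as.logical(cells$single_cell))
    } else warning("no 'single_cell' column; filter skipped")
  }
  counts <- counts[, keep_cell, drop = FALSE]
  cells <- cells[keep_cell, , drop = FALSE]
  # gene filters on the retained cells
  mol_stat <- if (qc$molecule_filter == "per_cell_max")
    apply(counts, 1L, max) else rowSums(counts)
  fail_mol <- mol_stat >= qc$max_molecules
  lib <- if ("total_molecules" %in% names(cells)) cells$total_molecules
         else colSums(counts)
  med_lcpm <- apply(log_cpm(counts, lib), 1L, median)
  fail_cpm <- med_lcpm < qc$min_median_log_cpm
  report[[length(report) + 1L]] <- data.frame(criterion = "gene_molecules",
                                              removed = sum(fail_mol))
  report[[length(report) + 1L]] <- data.frame(criterion = "gene_median_log_cpm",
                                              removed = sum(fail_cpm & !fail_mol))
  keep_gene <- !(fail_mol | fail_cpm)
  out <- list(counts = counts[keep_gene, , drop = FALSE],
              cells = cells,
              genes = bundle$genes[keep_gene, , drop = FALSE])
  list(bundle = out, report = do.call(rbind, report))
}

#' Read genotype dosages
#'
#' TSV layout: first column `individual`, remaining columns one variant
#' each, dosage values in `[0, 2]`. A companion map TSV supplies variant
#' positions (columns `variant`, `chrom`, `pos`; 1-based).
#'
#' @param dosage_path dosage TSV.
#' @param map_path variant map TSV.
#' @param maf_threshold drop variants below this minor allele frequency
#'   (default 0.05); `0` keeps everything.
#' @return List with `dosages`, `map`, `maf` as used by [cis_scan()].
#' @export
read_dosages <- function(dosage_path, map_path, maf_threshold = 0.05) {
  d <- read_tsv(dosage_path)
  map <- read_tsv(map_path)
  dos <- as.matrix(d[, -1L, drop = FALSE])
  rownames(dos) <- d[[1L]]
  if (any(dos < 0 | dos > 2, na.rm = TRUE)) stop_input("dosages must lie in [0, 2]")
  miss <- setdiff(colnames(dos), map$variant)
  if (length(miss)) stop_input("variants missing from map: %s",
                               paste(head(miss, 3L), collapse = ", "))
  map <- map[match(colnames(dos), map$variant), , drop = FALSE]
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_threshold
  list(dosages = dos[, keep, drop = FALSE],
       map = map[keep, , drop = FALSE], maf = maf[keep])
}

#' Read genotype dosages from a VCF with a DS FORMAT field
#'
#' Requires the `vcfR` package.
#'
#' @param vcf_path path to a (possibly compressed) VCF.
#' @param maf_threshold as in [read_dosages()].
#' @return List with `dosages`, `map`, `maf`.
#' @export
read_dosages_vcf <- function(vcf_path, maf_threshold = 0.05) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_input("reading VCF dosages requires the 'vcfR' package")
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  fix <- vcfR::getFIX(v)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  dos <- t(ds)
  colnames(dos) <- ids
  map <- data.frame(variant = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  keep <- maf >= maf_threshold
  list(dosages = dos[, keep, drop = FALSE], map = map[keep, , drop = FALSE],
       maf = maf[keep])
}

#' Write a phenotype matrix as a QTLtools-style BED table
#'
#' Layout: `#chr`, `start`, `end`, `gene`, `info`, `strand`, then one column
#' per individual. Positions are written 1-based inclusive (`start` = TSS),
#' which deviates from BED's 0-based half-open convention -- this is the
#' layout cis-QTL tools expect and is flagged here deliberately.
#'
#' @param pheno individuals x genes matrix.
#' @param annotation data.frame with `gene`, `chrom`, `tss`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_phenotype_bed <- function(pheno, annotation, path) {
  pheno <- as.matrix(pheno)
  ann <- annotation[match(colnames(pheno), annotation$gene), , drop = FALSE]
  df <- data.frame(`#chr` = ann$chrom, start = ann$tss, end = ann$tss,
                   gene = ann$gene, info = ".", strand = "+",
                   check.names = FALSE, stringsAsFactors = FALSE)
  tp <- t(pheno)
  colnames(tp) <- rownames(pheno)
  write_tsv_det(cbind(df, as.data.frame(tp)), path)
}

#' Read a QTLtools-style phenotype BED table
#'
#' @param path file written by [write_phenotype_bed()].
#' @return List with `pheno` (individuals x genes) and `annotation`.
#' @export
read_phenotype_bed <- function(path) {
  d <- read_tsv(path)
  meta <- d[, 1:6]
  ph <- t(as.matrix(d[, -(1:6), drop = FALSE]))
  colnames(ph) <- d$gene
  list(pheno = ph,
       annotation = data.frame(gene = d$gene, chrom = meta[[1L]],
                               tss = meta$start, stringsAsFactors = FALSE))
}

#' Write/read an individuals x genes phenotype matrix as TSV
#'
#' First column `individual`, one column per gene; values at 6 significant
#' digits.
#'
#' @param pheno individuals x genes matrix.
#' @param path file path.
#' @return `write_phenotype_matrix`: invisibly the path;
#'   `read_phenotype_matrix`: the matrix.
#' @export
write_phenotype_matrix <- function(pheno, path) {
  df <- data.frame(individual = rownames(pheno), as.matrix(pheno),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_det(df, path)
}

#' @rdname write_phenotype_matrix
#' @export
read_phenotype_matrix <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}
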