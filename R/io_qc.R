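# Reading/writing 10x-convention count bundles, cell-level QC filtering and
# per-cell log normalisation.

.find_bundle_file <- function(path, candidates) {
  for (f in candidates) {
    p <- file.path(path, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

# gzfile() reads plain files transparently as well; the opened connection is
# handed to the reader and closed here.
.with_maybe_gz <- function(path, reader) {
  con <- gzfile(path, open = "r")
  on.exit(close(con))
  reader(con)
}

#' Read a 10x-convention count bundle
#'
#' Expects `matrix.mtx`, `features.tsv` (or `genes.tsv`) and `barcodes.tsv`
#' in `path`, each optionally gzipped. The on-disk matrix is genes x cells
#' (Cell Ranger convention); the returned matrix is cells x genes with
#' barcode rownames and gene-symbol colnames.
#'
#' @param path Directory containing the bundle.
#' @return Sparse cells x genes count matrix (`dgCMatrix`).
#' @export
read_10x <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  mtx <- .find_bundle_file(path, c("matrix.mtx", "matrix.mtx.gz"))
  if (is.null(mtx)) stop("matrix.mtx(.gz) not found in ", path)
  feat <- .find_bundle_file(
    path, c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  if (is.null(feat)) stop("features.tsv(.gz)/genes.tsv(.gz) not found in ", path)
  bc <- .find_bundle_file(path, c("barcodes.tsv", "barcodes.tsv.gz"))
  if (is.null(bc)) stop("barcodes.tsv(.gz) not found in ", path)

  m <- .with_maybe_gz(mtx, Matrix::readMM)
  features <- .with_maybe_gz(feat, function(con)
    utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE))
  barcodes <- .with_maybe_gz(bc, function(con)
    utils::read.delim(con, header = FALSE, stringsAsFactors = FALSE))[[1]]
  if (nrow(features) != nrow(m))
    stop(sprintf("%s: matrix.mtx header says %d genes but %s has %d rows",
                 basename(mtx), nrow(m), basename(feat), nrow(features)))
  if (length(barcodes) != ncol(m))
    stop(sprintf("%s: matrix.mtx header says %d cells but %s has %d rows",
                 basename(mtx), ncol(m), basename(bc), length(barcodes)))
  symbols <- if (ncol(features) >= 2) features[[2]] else features[[1]]
  counts <- methods::as(Matrix::t(m), "CsparseMatrix")
  dimnames(counts) <- list(barcodes, symbols)
  counts
}

#' Write a 10x-convention count bundle
#'
#' Writes `matrix.mtx` (genes x cells, Matrix Market coordinate),
#' `features.tsv` (gene id and symbol) and `barcodes.tsv`.
#'
#' @param counts Sparse cells x genes count matrix with dimnames.
#' @param path Output directory (created if absent).
#' @param gzip Gzip the three files (`.gz` suffix added).
#' @return `path`, invisibly.
#' @export
write_10x <- function(counts, path, gzip = FALSE) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts needs cell rownames and gene colnames")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(path, "matrix.mtx")
  Matrix::writeMM(methods::as(Matrix::t(counts), "CsparseMatrix"), mtx)
  genes <- colnames(counts)
  utils::write.table(data.frame(id = genes, symbol = genes),
                     file.path(path, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
  if (gzip) {
    for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv")) {
      src <- file.path(path, f)
      con <- gzfile(paste0(src, ".gz"), "wb")
      writeBin(readBin(src, "raw", file.info(src)$size), con)
      close(con)
      unlink(src)
    }
  }
  invisible(path)
}

#' Quality-control configuration
#'
#' Defaults implement the droplet scRNA-seq cell filter used throughout the
#' package: cells with fewer than 200 or more than 7,500 expressed genes, or
#' with more than 5% mitochondrial counts, are removed. All inequalities are
#' strict, so boundary cells (exactly 200 or 7,500 genes, exactly 5% mito)
#' are retained.
#'
#' @param min_genes,max_genes Expressed-gene bounds (count > 0 defines
#'   "expressed").
#' @param max_mito Maximum tolerated mitochondrial fraction of a cell's total
#'   counts.
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes
#'   (case-sensitive; human HGNC convention).
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes = 200, max_genes = 7500, max_mito = 0.05,
                      mito_prefix = "MT-") {
  if (min_genes > max_genes) stop("min_genes must be <= max_genes")
  if (max_mito < 0 || max_mito > 1) stop("max_mito must lie in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito = max_mito, mito_prefix = mito_prefix),
            class = "qc_config")
}

#' Per-cell QC metrics
#'
#' @param counts Sparse cells x genes count matrix.
#' @param mito_prefix Mitochondrial gene-symbol prefix.
#' @return Data frame with `cell`, `n_genes` (genes with count > 0),
#'   `total_counts`, `mito_fraction` (0 for all-zero cells).
#' @export
qc_metrics <- function(counts, mito_prefix = "MT-") {
  n_genes <- Matrix::rowSums(counts > 0)
  total <- Matrix::rowSums(counts)
  mito_idx <- startsWith(colnames(counts), mito_prefix)
  mito_counts <- if (any(mito_idx))
    Matrix::rowSums(counts[, mito_idx, drop = FALSE]) else rep(0, nrow(counts))
  mito_fraction <- ifelse(total > 0, mito_counts / total, 0)
  data.frame(cell = rownames(counts), n_genes = as.integer(n_genes),
             total_counts = as.numeric(total),
             mito_fraction = as.numeric(mito_fraction),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter cells on expressed-gene and mitochondrial-fraction thresholds
#'
#' A cell is removed if its number of expressed genes is strictly below
#' `min_genes` or strictly above `max_genes`, or if its mitochondrial count
#' fraction strictly exceeds `max_mito`. Genes are never removed. An
#' all-zero cell has mitochondrial fraction 0 by definition and falls to the
#' `min_genes` rule.
#'
#' @param counts Sparse cells x genes count matrix.
#' @param cfg A [qc_config()].
#' @param meta Optional per-cell annotation data frame with columns `cell`
#'   and `donor`; enables per-donor removal counts in the report.
#' @return List with `counts` (filtered matrix), `meta` (filtered annotation,
#'   if supplied) and `report` (cells removed per criterion, overall and per
#'   donor; criteria counts are non-exclusive).
#' @export
qc_filter <- function(counts, cfg = qc_config(), meta = NULL) {
  if (nrow(counts) == 0L) stop("count matrix has zero cells")
  qm <- qc_metrics(counts, cfg$mito_prefix)
  low <- qm$n_genes < cfg$min_genes
  high <- qm$n_genes > cfg$max_genes
  mito <- qm$mito_fraction > cfg$max_mito
  keep <- !(low | high | mito)
  report <- list(
    config = unclass(cfg),
    n_input = nrow(counts),
    n_removed = sum(!keep),
    n_removed_low_genes = sum(low),
    n_removed_high_genes = sum(high),
    n_removed_mito = sum(mito),
    n_kept = sum(keep),
    mito_unit = "UMI counts")
  out <- list(counts = counts[keep, , drop = FALSE], report = report)
  if (!is.null(meta)) {
    if (!all(c("cell", "donor") %in% names(meta)))
      stop("meta needs columns 'cell' and 'donor'")
    donor <- meta$donor[match(rownames(counts), meta$cell)]
    per_donor <- t(vapply(
      split(seq_len(nrow(counts)), donor),
      function(i) c(n_input = length(i), n_removed = sum(!keep[i]),
                    low_genes = sum(low[i]), high_genes = sum(high[i]),
                    mito = sum(mito[i])),
      numeric(5)))
    out$report$per_donor <- as.data.frame(per_donor)
    out$meta <- meta[match(rownames(out$counts), meta$cell), , drop = FALSE]
    rownames(out$meta) <- NULL
  }
  out
}

#' Per-cell scaled log normalisation
#'
#' Computes `ln(1 + count / cell_total * scale)` for every entry; with the
#' default `scale = 1e6` the de-logged values are counts per million, the
#' UMI analogue of TPM (3' droplet counts carry no gene-length component).
#' Zeros map to zeros, so the sparsity pattern is preserved, and for every
#' cell the identity `sum(exp(value) - 1) == scale` holds.
#'
#' @param counts Sparse cells x genes count matrix; every cell must have
#'   total count > 0.
#' @param scale Library-size target (default 1e6).
#' @return Sparse cells x genes matrix of normalised values, with attributes
#'   `scale` and `log` recording the transformation.
#' @export
normalize_counts <- function(counts, scale = 1e6) {
  if (scale <= 0) stop("scale must be > 0")
  total <- Matrix::rowSums(counts)
  if (any(total == 0))
    stop(sum(total == 0), " cell(s) have zero total counts; ",
         "run qc_filter() before normalising")
  norm <- methods::as(counts, "CsparseMatrix") * 1.0
  # dgCMatrix @i holds 0-based row (cell) indices of the nonzeros.
  norm@x <- log1p(norm@x * scale / total[norm@i + 1L])
  attr(norm, "scale") <- scale
  attr(norm, "log") <- "ln(1+x)"
  norm
}
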