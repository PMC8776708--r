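# One-vs-rest marker statistics, gene-signature scores, dot-plot summaries
# and a generic over-representation test.

#' One-vs-rest Wilcoxon marker statistics for a cluster
#'
#' For every gene expressed in at least `min_pct` of the cluster's cells or
#' of the remaining cells, compares normalised expression in the cluster
#' against all other cells with a two-sided Wilcoxon rank-sum test (exact for
#' small tie-free samples; otherwise the normal approximation with midrank
#' tie correction and continuity correction), reporting the log fold-change
#' on de-logged means with pseudocount 1:
#' `logFC = ln((mean_in(exp(v)-1) + 1) / (mean_out(exp(v)-1) + 1))`.
#' P-values are Bonferroni-adjusted over the tested genes.
#'
#' @param norm Normalised cells x genes matrix from [normalize_counts()].
#' @param labels Cluster label per cell (length `nrow(norm)`).
#' @param cluster Cluster to test against the rest.
#' @param min_pct Minimum expressed fraction in either group for a gene to be
#'   tested.
#' @return Data frame ordered by p-value with columns `gene`, `logFC`, `p`,
#'   `p_adj`, `pct_in`, `pct_out`.
#' @export
find_markers <- function(norm, labels, cluster, min_pct = 0.1) {
  if (length(labels) != nrow(norm))
    stop("labels must have one entry per cell")
  if (!cluster %in% labels) stop("cluster '", cluster, "' absent from labels")
  in_cl <- labels == cluster
  if (sum(in_cl) < 2L || sum(!in_cl) < 2L)
    stop("need at least 2 cells in and out of the cluster")
  x_in <- norm[in_cl, , drop = FALSE]
  x_out <- norm[!in_cl, , drop = FALSE]
  pct_in <- Matrix::colMeans(x_in > 0)
  pct_out <- Matrix::colMeans(x_out > 0)
  test <- which(pct_in >= min_pct | pct_out >= min_pct)
  if (!length(test)) stop("no gene passes the min_pct filter")

  p <- numeric(length(test))
  lfc <- numeric(length(test))
  for (j in seq_along(test)) {
    g <- test[j]
    vi <- x_in[, g]
    vo <- x_out[, g]
    p[j] <- if (all(vi == vo[1]) && all(vo == vo[1])) 1 else
      stats::wilcox.test(vi, vo)$p.value
    lfc[j] <- log((mean(expm1(vi)) + 1) / (mean(expm1(vo)) + 1))
  }
  res <- data.frame(
    gene = colnames(norm)[test], logFC = lfc, p = p,
    p_adj = pmin(p * length(test), 1),
    pct_in = pct_in[test], pct_out = pct_out[test],
    stringsAsFactors = FALSE, row.names = NULL)
  res[order(res$p, -abs(res$logFC)), , drop = FALSE]
}

#' Per-cell gene-signature score
#'
#' The mean normalised expression over the signature genes present in the
#' matrix, per cell. Signature genes missing from the matrix are dropped and
#' reported in the `missing` attribute; gene order does not matter.
#'
#' @param norm Normalised cells x genes matrix.
#' @param genes Character vector of signature gene symbols (case-sensitive).
#' @return Named numeric vector of per-cell scores with attribute `missing`.
#' @export
signature_score <- function(norm, genes) {
  genes <- unique(genes)
  if (!length(genes)) stop("signature is empty")
  present <- intersect(genes, colnames(norm))
  if (!length(present)) stop("no signature gene present in the matrix")
  score <- Matrix::rowMeans(norm[, present, drop = FALSE])
  score <- stats::setNames(as.numeric(score), rownames(norm))
  attr(score, "missing") <- setdiff(genes, present)
  score
}

#' Dot-plot summary: percent expressed and average expression per cluster
#'
#' For genes: percent expressed is 100 x the fraction of the cluster's cells
#' with nonzero value, average expression the mean normalised value. For
#' signatures (named list of gene vectors): the per-cell [signature_score()]
#' takes the place of the gene value, with "expressed" meaning score > 0.
#'
#' @param norm Normalised cells x genes matrix.
#' @param labels Cluster label per cell.
#' @param genes Character vector of genes to summarise (optional).
#' @param signatures Named list of signature gene vectors (optional).
#' @return Data frame with `cluster`, `feature`, `pct_expressed` (0..100),
#'   `avg_expression`.
#' @export
dotplot_summary <- function(norm, labels, genes = NULL, signatures = NULL) {
  if (length(labels) != nrow(norm))
    stop("labels must have one entry per cell")
  labels <- as.factor(labels)
  if (any(table(labels) == 0L)) stop("empty cluster in labels")
  if (is.null(genes) && is.null(signatures))
    stop("supply genes and/or signatures")
  feats <- list()
  if (!is.null(genes)) {
    missing <- setdiff(genes, colnames(norm))
    if (length(missing)) stop("genes absent from matrix: ",
                              paste(missing, collapse = ", "))
    for (g in genes) feats[[g]] <- as.numeric(norm[, g])
  }
  if (!is.null(signatures)) {
    if (is.null(names(signatures))) stop("signatures must be a named list")
    for (s in names(signatures))
      feats[[s]] <- as.numeric(signature_score(norm, signatures[[s]]))
  }
  out <- expand.grid(cluster = levels(labels), feature = names(feats),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$pct_expressed <- NA_real_
  out$avg_expression <- NA_real_
  for (i in seq_len(nrow(out))) {
    v <- feats[[out$feature[i]]][labels == out$cluster[i]]
    out$pct_expressed[i] <- 100 * mean(v > 0)
    out$avg_expression[i] <- mean(v)
  }
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric probability of observing at least the observed
#' overlap between a query gene set and each term gene set, drawn from a
#' common universe; fold enrichment is
#' `(overlap/|query|) / (|term|/|universe|)`. P-values are
#' Benjamini-Hochberg-adjusted across terms.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `universe`).
#' @param terms A single character vector, or a named list of term gene sets
#'   (each intersected with the universe).
#' @param universe Character vector of all eligible genes.
#' @return Data frame with `term`, `n_term`, `overlap`, `expected`,
#'   `fold_enrichment`, `p`, `p_adj`.
#' @export
enrichment_test <- function(query, terms, universe) {
  query <- unique(query)
  universe <- unique(universe)
  if (!length(query)) stop("query is empty")
  if (!all(query %in% universe))
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  if (!is.list(terms)) terms <- list(term = terms)
  if (is.null(names(terms))) names(terms) <- paste0("term", seq_along(terms))
  rows <- lapply(names(terms), function(nm) {
    term <- intersect(unique(terms[[nm]]), universe)
    ov <- length(intersect(query, term))
    expected <- length(query) * length(term) / length(universe)
    data.frame(
      term = nm, n_term = length(term), overlap = ov, expected = expected,
      fold_enrichment = if (expected > 0) ov / expected else NA_real_,
      p = stats::phyper(ov - 1, length(term),
                        length(universe) - length(term), length(query),
                        lower.tail = FALSE),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}
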