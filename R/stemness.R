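# Reference-based per-cell stemness score and its group-wise comparisons.
#
# The score compares each cell against a stem-vs-fibroblast differential
# expression reference: the top up-regulated ("stem") and down-regulated
# ("fibroblast") genes each define an identity
#   identity = n + sum(log expression)
# (n = number of the listed genes the cell expresses, the sum taken over the
# listed genes' normalised values), and
#   stemness = (stem identity + 1) / (fibroblast identity + 1).

#' Select stemness signature genes from a differential-expression reference
#'
#' Restricts the reference to significant rows (`p_adj < alpha`), then takes
#' the `k` largest positive effects as the up ("stem") list and the `k` most
#' negative effects as the down ("fibroblast") list. Ties at the k-th rank
#' break deterministically by ascending `p_adj`, then lexicographic symbol.
#' If fewer than `k` significant genes exist in a direction, all available
#' are returned with a warning.
#'
#' @param ref Data frame with columns `symbol`, `effect` (positive = up in
#'   stem cells), `p_adj`.
#' @param k Genes to select per direction (default 250).
#' @param alpha Significance threshold on `p_adj`.
#' @return List with `up` and `down` character vectors.
#' @export
select_signature_genes <- function(ref, k = 250, alpha = 0.05) {
  if (k <= 0) stop("k must be a positive integer")
  if (!nrow(ref)) stop("reference table is empty")
  stopifnot(all(c("symbol", "effect", "p_adj") %in% names(ref)))
  if (anyDuplicated(ref$symbol)) stop("reference has duplicated symbols")
  sig <- ref[ref$p_adj < alpha, , drop = FALSE]
  pick <- function(rows, decreasing) {
    ord <- order(if (decreasing) -rows$effect else rows$effect,
                 rows$p_adj, rows$symbol)
    rows$symbol[ord][seq_len(min(k, nrow(rows)))]
  }
  up <- pick(sig[sig$effect > 0, , drop = FALSE], decreasing = TRUE)
  down <- pick(sig[sig$effect < 0, , drop = FALSE], decreasing = FALSE)
  if (length(up) < k)
    warning(sprintf("only %d significant up-regulated genes (k = %d)",
                    length(up), k))
  if (length(down) < k)
    warning(sprintf("only %d significant down-regulated genes (k = %d)",
                    length(down), k))
  list(up = up, down = down)
}

#' Per-cell stemness score
#'
#' For each cell and each gene list (up = stem, down = fibroblast) computes
#' `n`, the number of listed genes with raw count > 0, and the cumulative
#' log expression over the listed genes; their sum is the identity, and the
#' score is `(stem_identity + 1) / (fibroblast_identity + 1)`. With the
#' default `sum_mode = "all"` the cumulative term is the sum of normalised
#' values `ln(1 + count/total * scale)` over all listed genes (zero counts
#' contribute 0); `sum_mode = "expressed"` instead sums `ln(count/total *
#' scale)` over expressed listed genes only, which admits negative
#' contributions from genes below one count per scale unit. Listed genes
#' absent from the matrix contribute nothing and are reported in the
#' `missing_up` / `missing_down` attributes.
#'
#' @param norm Normalised cells x genes matrix from [normalize_counts()].
#' @param up,down Character vectors: stem ("up") and fibroblast ("down")
#'   gene lists; each must intersect the matrix genes.
#' @param counts Optional raw count matrix with the same axes; defaults to
#'   deriving expression (count > 0) from `norm > 0`, which is equivalent.
#' @param sum_mode `"all"` (default) or `"expressed"`, see Details.
#' @return Data frame with one row per cell: `cell`, `n_up_expressed`,
#'   `sum_log_up`, `stem_identity`, `n_down_expressed`, `sum_log_down`,
#'   `fib_identity`, `score`.
#' @export
stemness_score <- function(norm, up, down, counts = NULL,
                           sum_mode = c("all", "expressed")) {
  sum_mode <- match.arg(sum_mode)
  up <- unique(up); down <- unique(down)
  if (!length(up) || !length(down)) stop("up and down lists must be non-empty")
  up_in <- intersect(up, colnames(norm))
  down_in <- intersect(down, colnames(norm))
  if (!length(up_in)) stop("no up-list gene present in the matrix")
  if (!length(down_in)) stop("no down-list gene present in the matrix")
  expressed <- if (is.null(counts)) norm > 0 else counts > 0

  side <- function(gl) {
    sub <- norm[, gl, drop = FALSE]
    n <- as.numeric(Matrix::rowSums(expressed[, gl, drop = FALSE]))
    s <- if (sum_mode == "all") {
      as.numeric(Matrix::rowSums(sub))
    } else {
      sub <- methods::as(sub, "CsparseMatrix")
      sub@x <- log(expm1(sub@x))   # ln(TPM) of the expressed entries
      as.numeric(Matrix::rowSums(sub))
    }
    list(n = n, s = s)
  }
  u <- side(up_in); d <- side(down_in)
  out <- data.frame(
    cell = rownames(norm),
    n_up_expressed = as.integer(u$n), sum_log_up = u$s,
    stem_identity = u$n + u$s,
    n_down_expressed = as.integer(d$n), sum_log_down = d$s,
    fib_identity = d$n + d$s,
    stringsAsFactors = FALSE, row.names = NULL)
  out$score <- (out$stem_identity + 1) / (out$fib_identity + 1)
  attr(out, "missing_up") <- setdiff(up, up_in)
  attr(out, "missing_down") <- setdiff(down, down_in)
  attr(out, "sum_mode") <- sum_mode
  out
}

#' Compare stemness scores between two groups
#'
#' Unpaired Wilcoxon rank-sum test on per-cell scores. With
#' `alternative = "greater"` the test is one-sided for scores in `level`
#' exceeding the other group; `"two.sided"` tests any shift.
#'
#' @param scores Numeric vector of per-cell scores.
#' @param grouping Two-level factor (or coercible) aligned with `scores`.
#' @param alternative `"two.sided"` or `"greater"`.
#' @param level Group treated as the first sample; defaults to the first
#'   factor level.
#' @return List with `statistic` (rank-sum W), `p.value`, `n` (group sizes),
#'   `alternative`.
#' @export
compare_stemness <- function(scores, grouping,
                             alternative = c("two.sided", "greater"),
                             level = NULL) {
  alternative <- match.arg(alternative)
  grouping <- as.factor(grouping)
  if (nlevels(grouping) != 2L) stop("grouping must have exactly two levels")
  if (length(scores) != length(grouping))
    stop("scores and grouping lengths differ")
  if (is.null(level)) level <- levels(grouping)[1]
  if (!level %in% levels(grouping)) stop("unknown level '", level, "'")
  x <- scores[grouping == level]
  y <- scores[grouping != level]
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 cells")
  w <- stats::wilcox.test(x, y, alternative = alternative)
  list(statistic = unname(w$statistic), p.value = w$p.value,
       n = c(length(x), length(y)), alternative = alternative,
       level = level)
}

#' One-vs-rest stemness comparison across populations
#'
#' Tests, one-sided, whether each population's scores exceed those of all
#' remaining cells pooled — the "highest-scoring population" analysis.
#'
#' @param scores Numeric per-cell scores.
#' @param populations Population label per cell.
#' @return Data frame with `population`, `median`, `median_rest`, `p`
#'   (one-sided greater), ordered by descending median.
#' @export
stemness_by_population <- function(scores, populations) {
  populations <- as.factor(populations)
  if (length(scores) != length(populations))
    stop("scores and populations lengths differ")
  rows <- lapply(levels(populations), function(pop) {
    x <- scores[populations == pop]
    y <- scores[populations != pop]
    data.frame(population = pop, median = stats::median(x),
               median_rest = stats::median(y),
               p = stats::wilcox.test(x, y, alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$median), , drop = FALSE]
}
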