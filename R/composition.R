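# Age-related cluster composition analysis: per-cluster Fisher's exact odds
# ratios (one cluster against all remaining cells pooled), Woolf logit
# confidence intervals, and per-donor fraction t-tests.

#' Cross-tabulate age group against cluster membership
#'
#' @param meta Per-cell annotation with columns `age_group` (values "young"
#'   and "old") and `cluster`.
#' @param cluster Cluster of interest.
#' @return Named integer vector `(a, b, c, d)`: old cells in/out of the
#'   cluster, then young cells in/out.
#' @export
composition_table <- function(meta, cluster) {
  stopifnot(all(c("age_group", "cluster") %in% names(meta)))
  if (!all(meta$age_group %in% c("young", "old")))
    stop("age_group must be 'young' or 'old'")
  if (!any(meta$age_group == "young") || !any(meta$age_group == "old"))
    stop("need at least one young and one old cell")
  if (!cluster %in% meta$cluster)
    stop("cluster '", cluster, "' absent from meta")
  old <- meta$age_group == "old"
  inc <- meta$cluster == cluster
  c(a = sum(old & inc), b = sum(old & !inc),
    c = sum(!old & inc), d = sum(!old & !inc))
}

#' Fisher's exact odds ratio for a 2x2 composition table
#'
#' The p-value is the two-sided Fisher exact probability (sum over all
#' tables with point probability at most the observed table's). The odds
#' ratio is the sample cross-product in the requested orientation:
#' `"old-enriched"` reports odds(old in cluster) / odds(young in cluster),
#' so OR > 1 reads "enriched in old"; `"young-enriched"` reports the
#' reciprocal so OR > 1 reads "enriched in young". The 95% CI uses the
#' Woolf logit method `exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`,
#' with the Haldane 0.5 continuity correction applied to all cells if and
#' only if any cell is zero. A conditional-MLE exact interval (from the
#' exact test's non-central hypergeometric likelihood) is available with
#' `ci_method = "exact"`.
#'
#' @param tab Table from [composition_table()], or any numeric `(a, b, c, d)`.
#' @param orientation `"old-enriched"` or `"young-enriched"`.
#' @param ci_method `"woolf"` (default) or `"exact"`.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row data frame: `a`, `b`, `c`, `d`, `orientation`, `OR`,
#'   `ci_low`, `ci_high`, `p`.
#' @export
fisher_or <- function(tab, orientation = c("old-enriched", "young-enriched"),
                      ci_method = c("woolf", "exact"), conf_level = 0.95) {
  orientation <- match.arg(orientation)
  ci_method <- match.arg(ci_method)
  stopifnot(length(tab) == 4L, all(tab >= 0), all(tab == round(tab)))
  a <- tab[[1]]; b <- tab[[2]]; cc <- tab[[3]]; d <- tab[[4]]
  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0)
    stop("empty row or column margin")
  m <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
  ft <- stats::fisher.test(m, conf.level = conf_level)
  or_old <- (a * d) / (b * cc)
  or <- if (orientation == "old-enriched") or_old else 1 / or_old
  if (ci_method == "woolf") {
    h <- if (any(c(a, b, cc, d) == 0)) 0.5 else 0
    lo <- log(((a + h) * (d + h)) / ((b + h) * (cc + h)))
    if (orientation == "young-enriched") lo <- -lo
    se <- sqrt(1 / (a + h) + 1 / (b + h) + 1 / (cc + h) + 1 / (d + h))
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    ci <- exp(lo + c(-1, 1) * z * se)
  } else {
    ci <- if (orientation == "old-enriched") ft$conf.int else
      rev(1 / ft$conf.int)
  }
  data.frame(a = a, b = b, c = cc, d = d, orientation = orientation,
             OR = or, ci_low = ci[1], ci_high = ci[2], p = ft$p.value,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-cluster composition shift analysis
#'
#' Runs [composition_table()] and [fisher_or()] for every cluster (each
#' against all remaining cells pooled). Unless orientations are supplied,
#' each cluster is reported in the direction of its observed enrichment
#' (OR >= 1).
#'
#' @param meta Per-cell annotation with `age_group` and `cluster`.
#' @param orientations Optional named character vector mapping cluster to
#'   `"old-enriched"` or `"young-enriched"`.
#' @param ... Passed to [fisher_or()].
#' @return Data frame with one row per cluster.
#' @export
composition_analysis <- function(meta, orientations = NULL, ...) {
  clusters <- sort(unique(meta$cluster))
  rows <- lapply(clusters, function(cl) {
    tab <- composition_table(meta, cl)
    ori <- if (!is.null(orientations) && cl %in% names(orientations)) {
      orientations[[cl]]
    } else {
      or_old <- (tab[["a"]] * tab[["d"]]) / (tab[["b"]] * tab[["c"]])
      if (is.nan(or_old) || or_old >= 1) "old-enriched" else "young-enriched"
    }
    cbind(cluster = cl, fisher_or(tab, orientation = ori, ...))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-donor cluster fractions
#'
#' @param meta Per-cell annotation with `donor`, `age_group`, `cluster`.
#' @param cluster Cluster of interest.
#' @return Data frame with `donor`, `age_group`, `n_cells`, `n_in_cluster`,
#'   `fraction`.
#' @export
donor_fractions <- function(meta, cluster) {
  stopifnot(all(c("donor", "age_group", "cluster") %in% names(meta)))
  if (!cluster %in% meta$cluster)
    stop("cluster '", cluster, "' absent from meta")
  sp <- split(meta, meta$donor)
  rows <- lapply(sp, function(m) data.frame(
    donor = m$donor[1], age_group = m$age_group[1], n_cells = nrow(m),
    n_in_cluster = sum(m$cluster == cluster),
    fraction = mean(m$cluster == cluster), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-tailed unpaired t-test on per-donor cluster fractions
#'
#' Student's pooled-variance t-test by default (`welch = TRUE` for unequal
#' variances), comparing young against old donors' fractions; also reports
#' each group's mean and standard error of the mean.
#'
#' @param fractions Numeric per-donor fractions.
#' @param groups Age group per donor ("young"/"old" or any two-level factor).
#' @param welch Use the Welch unequal-variance test.
#' @return List with `t`, `df`, `p.value`, and per-group `n`, `mean`, `sem`.
#' @export
fraction_test <- function(fractions, groups, welch = FALSE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  if (length(fractions) != length(groups))
    stop("fractions and groups lengths differ")
  if (any(table(groups) < 2L)) stop("need at least 2 donors per group")
  tt <- stats::t.test(fractions ~ groups, var.equal = !welch)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  by_group <- split(fractions, groups)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       n = vapply(by_group, length, integer(1)),
       mean = vapply(by_group, mean, numeric(1)),
       sem = vapply(by_group, sem, numeric(1)),
       method = if (welch) "Welch" else "Student")
}
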