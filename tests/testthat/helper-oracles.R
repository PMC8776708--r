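# Independent brute-force oracles used to cross-check the statistical
# routines: full enumeration for rank-sum and Fisher tests, direct loops for
# the stemness arithmetic.

# Exact Wilcoxon rank-sum p by enumerating every assignment of the combined
# values to the two groups. Two-sided tail chosen by comparing the observed
# Mann-Whitney U to its (symmetric) null mean, then doubled and capped.
enum_wilcox_p <- function(x, y, alternative = "two.sided") {
  m <- length(x); n <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  u_all <- apply(idx, 2, function(i) sum(r[i]) - m * (m + 1) / 2)
  if (alternative == "greater") {
    mean(u_all >= u_obs)
  } else {
    p <- if (u_obs > m * n / 2) mean(u_all >= u_obs) else mean(u_all <= u_obs)
    min(2 * p, 1)
  }
}

# Two-sided Fisher exact p by direct enumeration over the hypergeometric
# support with point probabilities computed from binomial coefficients:
# sum of P(table) over all tables (fixed margins) with P <= P(observed).
enum_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  pr <- choose(m1, support) * choose(m2, k - support) / choose(N, k)
  p_obs <- choose(m1, a) * choose(m2, c) / choose(N, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

# Stemness score of one cell by direct loops over the gene lists.
brute_stemness <- function(counts_row, norm_row, gene_names, up, down) {
  one_side <- function(gl) {
    n <- 0; s <- 0
    for (g in gl) {
      j <- which(gene_names == g)
      if (length(j) == 1) {
        if (counts_row[j] > 0) n <- n + 1
        s <- s + norm_row[j]
      }
    }
    n + s
  }
  stem <- one_side(up); fib <- one_side(down)
  list(stem = stem, fib = fib, score = (stem + 1) / (fib + 1))
}

# Shared small cohort for tests that only need a realistic matrix.
local_small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(cells_per_donor = 300, n_genes = 600, seed = 101)
      cache <<- generate_cohort(spec)
    }
    cache
  }
})

# Build a tiny cells x genes sparse matrix from a dense one with names.
as_counts <- function(m, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- sprintf("cell%d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(ncol(m)))
  out <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  dimnames(out) <- list(cells, genes)
  out
}
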