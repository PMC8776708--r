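test_that("marker Wilcoxon p agrees with exact enumeration on small tie-free splits", {
  set.seed(77)
  for (total in c(6, 8, 10)) {
    for (m in 2:(total - 2)) {
      vals <- sample(seq_len(40), total)  # distinct values, no ties
      labels <- rep(c("A", "B"), c(m, total - m))
      # gene of interest plus a ubiquitous filler so min_pct passes trivially
      norm <- as_counts(cbind(vals, rep(1, total)))
      res <- find_markers(norm, labels, "A", min_pct = 0)
      p_pkg <- res$p[res$gene == "g1"]
      p_oracle <- enum_wilcox_p(vals[labels == "A"], vals[labels == "B"])
      expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
    }
  }
})

test_that("a gene with identical values in both groups is a null marker", {
  norm <- as_counts(cbind(rep(2.5, 8), c(1:4, 8:5)))
  labels <- rep(c("A", "B"), each = 4)
  res <- find_markers(norm, labels, "A", min_pct = 0)
  expect_equal(res$p[res$gene == "g1"], 1)
  expect_equal(res$logFC[res$gene == "g1"], 0)
  expect_true(res$p_adj[res$gene == "g1"] >= res$p[res$gene == "g1"])
})

test_that("planted fold-8 markers are detected with positive logFC", {
  pops <- list(
    population_spec("F4a", 0.5, 0.5,
                    program = data.frame(gene = 1:3, fc = 8)),
    population_spec("rest", 0.5, 0.5))
  spec <- synthetic_spec(n_young_donors = 1, n_old_donors = 1,
                         cells_per_donor = 150, populations = pops,
                         n_genes = 400, n_mito = 0, seed = 55)
  co <- generate_cohort(spec)
  norm <- normalize_counts(co$counts[Matrix::rowSums(co$counts) > 0, ])
  labels <- co$meta$cluster[Matrix::rowSums(co$counts) > 0]
  expect_gte(min(table(labels)), 100)
  res <- find_markers(norm, labels, "F4a")
  planted <- res[res$gene %in% co$truth$markers$F4a, ]
  expect_equal(nrow(planted), 3)
  expect_true(all(planted$p_adj < 0.05))
  expect_true(all(planted$logFC > 0))
  expect_error(find_markers(norm, labels, "absent"), "absent")
})

test_that("signature scores are per-cell means, order-invariant, planted program highest in F4a", {
  m <- rbind(c(0, 0, 5), c(2, 4, 0))
  norm <- normalize_counts(as_counts(m))
  # single-gene signature equals that gene's normalised value
  expect_equal(as.numeric(signature_score(norm, "g1")), as.numeric(norm[, 1]))
  # zero counts at all signature genes -> score 0
  expect_equal(unname(signature_score(norm, c("g1", "g2"))[1]), 0)
  # gene order does not matter; missing genes reported
  s1 <- signature_score(norm, c("g1", "g2", "nope"))
  s2 <- signature_score(norm, c("g2", "nope", "g1"))
  expect_equal(unname(s1), unname(s2))
  expect_equal(attr(s1, "missing"), "nope")
  expect_error(signature_score(norm, c("nope1", "nope2")), "no signature gene")

  co <- local_small_cohort()
  keep <- Matrix::rowSums(co$counts) > 0
  nm <- normalize_counts(co$counts[keep, ])
  ds <- signature_score(nm, co$truth$markers$F4a)
  by_pop <- tapply(ds, co$meta$cluster[keep], mean)
  expect_equal(names(which.max(by_pop)), "F4a")
})

test_that("dot-plot summaries match direct per-cluster arithmetic", {
  m <- rbind(c(1, 0, 3), c(0, 0, 2), c(4, 0, 0), c(2, 2, 2), c(0, 1, 1),
             c(3, 3, 3))
  norm <- normalize_counts(as_counts(m))
  labels <- c("c1", "c1", "c2", "c2", "c3", "c3")
  out <- dotplot_summary(norm, labels, genes = c("g1", "g2", "g3"))
  for (i in seq_len(nrow(out))) {
    v <- as.numeric(norm[labels == out$cluster[i], out$feature[i]])
    expect_equal(out$pct_expressed[i], 100 * mean(v > 0))
    expect_equal(out$avg_expression[i], mean(v))
  }
  # gene absent in a cluster -> (0, 0); expressed in every cell -> 100
  g2c1 <- out[out$cluster == "c1" & out$feature == "g2", ]
  expect_equal(g2c1$pct_expressed, 0)
  expect_equal(g2c1$avg_expression, 0)
  g3c3 <- out[out$cluster == "c3" & out$feature == "g3", ]
  expect_equal(g3c3$pct_expressed, 100)

  # signature summaries use the per-cell score
  sig <- dotplot_summary(norm, labels, signatures = list(s = c("g1", "g3")))
  sc <- signature_score(norm, c("g1", "g3"))
  expect_equal(sig$avg_expression[sig$cluster == "c1"],
               mean(sc[labels == "c1"]))
  expect_error(dotplot_summary(norm, factor(labels, levels = c(unique(labels), "empty")),
                               genes = "g1"),
               "empty cluster")
})

test_that("over-representation p matches hypergeometric enumeration", {
  universe <- sprintf("u%03d", 1:60)
  term <- universe[1:12]
  # query equal to the term: the minimal achievable p for these sizes
  res <- enrichment_test(term, term, universe)
  p_oracle <- choose(12, 12) * choose(48, 0) / choose(60, 12)
  expect_equal(res$p, p_oracle, tolerance = 1e-12)

  # random query: upper tail equals direct enumeration over the support
  set.seed(3)
  for (i in 1:20) {
    q <- sample(universe, sample(5:25, 1))
    ov <- length(intersect(q, term))
    res_i <- enrichment_test(q, term, universe)
    support <- ov:min(length(q), 12)
    p_enum <- sum(choose(12, support) * choose(48, length(q) - support)) /
      choose(60, length(q))
    expect_equal(res_i$p, p_enum, tolerance = 1e-10)
    expect_equal(res_i$overlap, ov)
  }

  # disjoint query and term -> overlap 0, p = 1, fold enrichment 0
  res0 <- enrichment_test(universe[13:20], term, universe)
  expect_equal(res0$p, 1)
  expect_equal(res0$fold_enrichment, 0)

  # overlap equal to the expected count -> fold enrichment exactly 1
  q <- c(universe[1], universe[13:16])  # 5 of 60, term 12 -> expected 1
  res1 <- enrichment_test(q, term, universe)
  expect_equal(res1$fold_enrichment, 1)

  # BH adjustment across terms, monotone with p
  terms <- list(t1 = term, t2 = universe[1:30], t3 = universe[55:60])
  multi <- enrichment_test(universe[1:10], terms, universe)
  expect_equal(multi$p_adj, stats::p.adjust(multi$p, "BH"))
  expect_error(enrichment_test(c("zzz"), term, universe), "outside")
})
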