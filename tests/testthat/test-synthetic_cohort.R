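test_that("cohort generation is deterministic and respects the donor layout", {
  spec <- synthetic_spec(n_young_donors = 2, n_old_donors = 2,
                         cells_per_donor = 100, n_genes = 300, seed = 5)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$counts, co2$counts)
  expect_identical(co1$meta, co2$meta)

  expect_equal(sum(co1$meta$age_group == "young"), 2 * 100)
  expect_equal(sum(co1$meta$age_group == "old"), 2 * 100)
  expect_false(anyDuplicated(co1$meta$cell) > 0)
  pop_names <- vapply(spec$populations, `[[`, character(1), "name")
  expect_true(all(co1$meta$cluster %in% pop_names))
  # every cell has exactly one label, aligned with the matrix
  expect_identical(co1$meta$cell, rownames(co1$counts))
  expect_identical(unname(co1$truth$labels), co1$meta$cluster)
  # counts are non-negative integers
  expect_true(all(co1$counts@x >= 0))
  expect_true(all(co1$counts@x == round(co1$counts@x)))

  # a different seed changes the draw
  co3 <- generate_cohort(synthetic_spec(n_young_donors = 2, n_old_donors = 2,
                                        cells_per_donor = 100, n_genes = 300,
                                        seed = 6))
  expect_false(identical(co1$counts, co3$counts))
})

test_that("population fractions match membership probabilities within 3 binomial SDs", {
  # rare-population case at a realistic young group size
  pops <- list(population_spec("F4a", 0.034, 0.004935),
               population_spec("rest", 1 - 0.034, 1 - 0.004935))
  spec <- synthetic_spec(n_young_donors = 3, n_old_donors = 4,
                         cells_per_donor = c(6380, 6380, 6379,
                                             7753, 7753, 7752, 7752),
                         populations = pops, seed = 21)
  meta <- simulate_cohort_meta(spec)
  young <- meta[meta$age_group == "young", ]
  old <- meta[meta$age_group == "old", ]
  expect_equal(nrow(young), 19139)
  expect_equal(nrow(old), 31010)
  f_young <- mean(young$cluster == "F4a")
  sd_young <- sqrt(0.034 * (1 - 0.034) / nrow(young))
  expect_lt(abs(f_young - 0.034), 3 * sd_young)
  f_old <- mean(old$cluster == "F4a")
  sd_old <- sqrt(0.004935 * (1 - 0.004935) / nrow(old))
  expect_lt(abs(f_old - 0.004935), 3 * sd_old)

  # default five-population layout, per age group
  spec2 <- synthetic_spec(cells_per_donor = 3000, n_genes = 200, seed = 22)
  meta2 <- simulate_cohort_meta(spec2)
  for (age in c("young", "old")) {
    sub <- meta2[meta2$age_group == age, ]
    probs <- vapply(spec2$populations,
                    `[[`, numeric(1), if (age == "young") "prob_young" else "prob_old")
    names(probs) <- vapply(spec2$populations, `[[`, character(1), "name")
    for (pop in names(probs)) {
      f <- mean(sub$cluster == pop)
      s <- sqrt(probs[pop] * (1 - probs[pop]) / nrow(sub))
      expect_lt(abs(f - probs[pop]), 3 * s)
    }
  }
})

test_that("planted program fold-changes are recovered in population count means", {
  pops <- list(
    population_spec("A", 0.5, 0.5,
                    program = data.frame(gene = 1:5, fc = 4)),
    population_spec("B", 0.5, 0.5))
  spec <- synthetic_spec(n_young_donors = 2, n_old_donors = 2,
                         cells_per_donor = 1500, populations = pops,
                         n_genes = 300, n_mito = 0, donor_lib_sd = 0,
                         seed = 31)
  co <- generate_cohort(spec)
  in_a <- co$meta$cluster == "A"
  for (g in 1:5) {
    x_in <- co$counts[in_a, g]
    x_out <- co$counts[!in_a, g]
    ratio <- mean(x_in) / mean(x_out)
    se <- ratio * sqrt(stats::var(x_in) / (sum(in_a) * mean(x_in)^2) +
                       stats::var(x_out) / (sum(!in_a) * mean(x_out)^2))
    expect_lt(abs(ratio - 4), 3 * se)
  }
})

test_that("mitochondrial genes are MT- named and carry the expected count share", {
  spec <- synthetic_spec(cells_per_donor = 200, n_genes = 500,
                         mito_fraction_mean = 0.04, seed = 41)
  co <- generate_cohort(spec)
  mito <- startsWith(colnames(co$counts), "MT-")
  expect_equal(sum(mito), 13)
  qm <- qc_metrics(co$counts)
  expect_lt(abs(mean(qm$mito_fraction) - 0.04), 0.005)
})

test_that("invalid cohort specs are rejected", {
  expect_error(synthetic_spec(n_young_donors = 0), "at least one donor")
  expect_error(synthetic_spec(cells_per_donor = 0), "at least one cell")
  expect_error(synthetic_spec(dispersion = 0), "dispersion")
  expect_error(
    synthetic_spec(populations = list(population_spec("A", 0.6, 1),
                                      population_spec("B", 0.6, 0))),
    "sum to")
  expect_error(population_spec("A", 0.5, 0.5,
                               program = data.frame(gene = 1:2, fc = c(1, 0))),
               "strictly positive")
  expect_error(population_spec("A", 0.5, 0.5,
                               program = data.frame(gene = c(1, 1), fc = 2)),
               "unique")
})

test_that("reference DE generator plants exactly the requested sets, reproducibly", {
  genes <- cohort_gene_names(2000)
  ref1 <- generate_reference_de(genes, n_up = 250, n_down = 250, seed = 9)
  ref2 <- generate_reference_de(genes, n_up = 250, n_down = 250, seed = 9)
  expect_identical(ref1, ref2)
  expect_equal(nrow(ref1), 2000)
  expect_equal(sum(ref1$p_adj < 0.05), 500)

  # rank-based selection downstream recovers the planted sets exactly
  gl <- select_signature_genes(ref1, k = 250)
  expect_setequal(gl$up, attr(ref1, "planted_up"))
  expect_setequal(gl$down, attr(ref1, "planted_down"))

  # forced membership wires a population's program into the up set
  forced <- genes[61:100]
  ref3 <- generate_reference_de(genes, 250, 250, seed = 10, up_genes = forced)
  expect_true(all(forced %in% attr(ref3, "planted_up")))

  expect_error(generate_reference_de(genes[1:100], n_up = 60, n_down = 60),
               "exceeds")
})
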