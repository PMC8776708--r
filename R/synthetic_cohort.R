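# Synthetic aging scRNA-seq cohorts with known ground truth.
#
# The generator emulates the structure of a two-age-group human skin
# fibroblast study: several donors per age group, a handful of fibroblast
# populations (including a mesenchymal population split into subclusters
# 4a/4b), population-specific marker programs, and age-dependent shifts in
# population membership of a chosen odds-ratio magnitude. Counts are
# negative-binomial; "MT-"-named genes carry a configurable fraction of each
# cell's counts in expectation so that mitochondrial QC is exercised.

# Human mitochondrial protein-coding gene symbols (HGNC), used to name the
# planted mitochondrial genes.
.MT_SYMBOLS <- c(
  "MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6", "MT-CO3",
  "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6", "MT-CYB"
)

#' Describe one synthetic fibroblast population
#'
#' @param name Population label, e.g. `"F4a"`.
#' @param prob_young,prob_old Probability that a cell of the given age group
#'   belongs to this population. Probabilities across all populations must sum
#'   to 1 within each age group.
#' @param program Optional planted expression program: a data frame with
#'   columns `gene` (gene index into the cohort's gene vector), `fc`
#'   (multiplicative fold-change on the gene's baseline mean, > 0) and
#'   optionally `fc_old` (fold-change used for old cells of this population;
#'   defaults to `fc`, set lower to attenuate a program with age).
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, prob_young, prob_old, program = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (prob_young < 0 || prob_young > 1 || prob_old < 0 || prob_old > 1)
    stop("membership probabilities must lie in [0, 1]")
  if (!is.null(program)) {
    program <- as.data.frame(program)
    if (!all(c("gene", "fc") %in% names(program)))
      stop("program needs columns 'gene' and 'fc'")
    if (anyDuplicated(program$gene))
      stop("program gene indices must be unique within a population")
    if (is.null(program$fc_old)) program$fc_old <- program$fc
    if (any(program$fc <= 0) || any(program$fc_old <= 0))
      stop("fold-changes must be strictly positive")
  }
  structure(list(name = name, prob_young = prob_young, prob_old = prob_old,
                 program = program),
            class = "population_spec")
}

#' Default fibroblast population layout
#'
#' Five populations mirroring the reticular (F1), papillary (F2),
#' pro-inflammatory (F3) and mesenchymal (F4a dermal sheath, F4b) fibroblast
#' populations of aged human skin. Young membership probabilities are anchored
#' at plausible fractions; old probabilities are derived so that the
#' one-vs-rest odds ratios equal 1.685 (old-enriched, F1), 1.666 (F3), 7.097
#' (F4a) and 2.258 (F4b) (young-enriched), with the papillary population
#' absorbing the remainder. Each population carries a planted marker program;
#' the F4a program doubles as the dermal-sheath/stem program.
#'
#' @param marker_fc Fold-change of planted marker programs.
#' @return List of [population_spec()] objects.
#' @export
default_populations <- function(marker_fc = 4) {
  prog <- function(idx, fc) data.frame(gene = idx, fc = fc)
  list(
    population_spec("F1", 0.300, 0.4193279, program = prog(1:20, marker_fc)),
    population_spec("F2", 0.350, 0.3684112, program = prog(21:40, marker_fc)),
    population_spec("F3", 0.286, 0.1938141, program = prog(41:60, marker_fc)),
    population_spec("F4a", 0.034, 0.0049349, program = prog(61:100, marker_fc)),
    population_spec("F4b", 0.030, 0.0135119, program = prog(101:120, marker_fc))
  )
}

#' Specify a synthetic aging cohort
#'
#' @param n_young_donors,n_old_donors Number of donors per age group.
#' @param cells_per_donor Cells per donor; a single number, or a vector of
#'   length `n_young_donors + n_old_donors` (young donors first).
#' @param populations List of [population_spec()] objects.
#' @param n_genes Total number of genes (mitochondrial genes included).
#' @param baseline_mean Expected counts per gene per cell before fold-changes.
#' @param dispersion Negative-binomial size parameter (shared cohort-wide).
#' @param mito_fraction_mean Expected fraction of a cell's counts falling on
#'   "MT-"-named genes.
#' @param n_mito Number of mitochondrial genes (placed at the end of the gene
#'   vector and named with the "MT-" prefix).
#' @param donor_lib_sd Log-normal sd of the per-donor library-size factor
#'   (0 disables donor scaling).
#' @param age_effect Optional global age effect: a list with `genes` (indices)
#'   and `old_fold` (> 0), multiplying those genes' means in all old cells.
#' @param seed Master seed; per-donor substreams are derived from it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_young_donors = 3, n_old_donors = 4,
                           cells_per_donor = 1000,
                           populations = default_populations(),
                           n_genes = 2000, baseline_mean = 0.3,
                           dispersion = 2, mito_fraction_mean = 0.03,
                           n_mito = 13, donor_lib_sd = 0.1,
                           age_effect = NULL, seed = 1) {
  spec <- structure(
    list(n_young_donors = as.integer(n_young_donors),
         n_old_donors = as.integer(n_old_donors),
         cells_per_donor = as.integer(cells_per_donor),
         populations = populations, n_genes = as.integer(n_genes),
         baseline_mean = baseline_mean, dispersion = dispersion,
         mito_fraction_mean = mito_fraction_mean, n_mito = as.integer(n_mito),
         donor_lib_sd = donor_lib_sd, age_effect = age_effect,
         seed = as.integer(seed)),
    class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  if (spec$n_young_donors < 1L || spec$n_old_donors < 1L)
    stop("need at least one donor per age group")
  n_donors <- spec$n_young_donors + spec$n_old_donors
  if (!length(spec$cells_per_donor) %in% c(1L, n_donors))
    stop("cells_per_donor must have length 1 or one entry per donor")
  if (any(spec$cells_per_donor < 1L))
    stop("need at least one cell per donor")
  if (spec$dispersion <= 0) stop("dispersion must be > 0")
  if (spec$baseline_mean <= 0) stop("baseline_mean must be > 0")
  if (spec$mito_fraction_mean < 0 || spec$mito_fraction_mean > 1)
    stop("mito_fraction_mean must lie in [0, 1]")
  if (spec$n_mito < 0 || spec$n_mito >= spec$n_genes)
    stop("n_mito must be in [0, n_genes)")
  if (!length(spec$populations)) stop("need at least one population")
  py <- sum(vapply(spec$populations, `[[`, numeric(1), "prob_young"))
  po <- sum(vapply(spec$populations, `[[`, numeric(1), "prob_old"))
  if (abs(py - 1) > 1e-12)
    stop(sprintf("young membership probabilities sum to %.10f, not 1", py))
  if (abs(po - 1) > 1e-12)
    stop(sprintf("old membership probabilities sum to %.10f, not 1", po))
  for (p in spec$populations) {
    if (!is.null(p$program) && any(p$program$gene > spec$n_genes))
      stop("program gene index exceeds n_genes in population ", p$name)
  }
  if (!is.null(spec$age_effect)) {
    if (is.null(spec$age_effect$genes) || is.null(spec$age_effect$old_fold))
      stop("age_effect needs 'genes' and 'old_fold'")
    if (spec$age_effect$old_fold <= 0) stop("age_effect$old_fold must be > 0")
  }
  invisible(spec)
}

#' Gene symbols for a synthetic cohort
#'
#' Autosomal genes are named `G0001`, `G0002`, ...; the last `n_mito` genes
#' carry human mitochondrial symbols (`MT-ND1`, ...), extended with
#' `MT-X01`, ... if more than 13 are requested.
#' @param n_genes,n_mito As in [synthetic_spec()].
#' @return Character vector of length `n_genes`.
#' @export
cohort_gene_names <- function(n_genes, n_mito = 13) {
  stopifnot(n_mito < n_genes)
  nm <- sprintf("G%04d", seq_len(n_genes - n_mito))
  if (n_mito > 0) {
    mt <- .MT_SYMBOLS[seq_len(min(n_mito, length(.MT_SYMBOLS)))]
    if (n_mito > length(.MT_SYMBOLS))
      mt <- c(mt, sprintf("MT-X%02d", seq_len(n_mito - length(.MT_SYMBOLS))))
    nm <- c(nm, mt)
  }
  nm
}

# Donor layout: ids, age groups and per-donor cell counts.
.donor_layout <- function(spec) {
  n_donors <- spec$n_young_donors + spec$n_old_donors
  donors <- c(sprintf("young%d", seq_len(spec$n_young_donors)),
              sprintf("old%d", seq_len(spec$n_old_donors)))
  age <- rep(c("young", "old"), c(spec$n_young_donors, spec$n_old_donors))
  n_cells <- if (length(spec$cells_per_donor) == 1L)
    rep(spec$cells_per_donor, n_donors) else spec$cells_per_donor
  list(donors = donors, age = age, n_cells = n_cells)
}

# Derive one substream seed per donor from the master seed, so donor blocks
# are reproducible independent of how many cells other donors have.
.donor_seeds <- function(seed, n_donors) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_donors + 1L)
}

#' Draw cohort metadata only (no counts)
#'
#' Runs the donor/population assignment stage of [generate_cohort()] on its
#' own. Useful for composition analyses at realistic cohort sizes, where the
#' count matrix is not needed.
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame with columns `cell`, `donor`, `age_group`, `cluster`.
#' @export
simulate_cohort_meta <- function(spec) {
  validate_spec(spec)
  lay <- .donor_layout(spec)
  seeds <- .donor_seeds(spec$seed, length(lay$donors))
  pop_names <- vapply(spec$populations, `[[`, character(1), "name")
  py <- vapply(spec$populations, `[[`, numeric(1), "prob_young")
  po <- vapply(spec$populations, `[[`, numeric(1), "prob_old")
  out <- vector("list", length(lay$donors))
  for (d in seq_along(lay$donors)) {
    set.seed(seeds[d])
    prob <- if (lay$age[d] == "young") py else po
    cl <- sample(pop_names, lay$n_cells[d], replace = TRUE, prob = prob)
    out[[d]] <- data.frame(
      cell = sprintf("%s_cell%05d", lay$donors[d], seq_len(lay$n_cells[d])),
      donor = lay$donors[d], age_group = lay$age[d], cluster = cl,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic aging cohort
#'
#' Assigns each cell a donor, an age group and a population (drawn from the
#' age group's membership probabilities), then draws unique counts from a
#' negative binomial with log-normal gene baseline means multiplied by the
#' cell's population program fold-changes, a per-donor library-size factor
#' and, for old cells, any global age effect. Genes named with the "MT-"
#' prefix receive `mito_fraction_mean` of each cell's counts in expectation.
#' Identical spec and seed give bit-identical output.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `counts` (sparse cells x genes integer matrix), `meta`
#'   (per-cell donor/age/cluster data frame) and `truth` (planted ground
#'   truth: membership probabilities, per-population program genes, and the
#'   stem-program gene symbols taken from population "F4a" when present).
#' @export
generate_cohort <- function(spec) {
  validate_spec(spec)
  lay <- .donor_layout(spec)
  seeds <- .donor_seeds(spec$seed, length(lay$donors))
  genes <- cohort_gene_names(spec$n_genes, spec$n_mito)
  pop_names <- vapply(spec$populations, `[[`, character(1), "name")
  py <- vapply(spec$populations, `[[`, numeric(1), "prob_young")
  po <- vapply(spec$populations, `[[`, numeric(1), "prob_old")

  # Gene baseline means: log-normal with expectation baseline_mean, then the
  # mitochondrial block rescaled so its share of the expected library equals
  # mito_fraction_mean.
  set.seed(seeds[length(seeds)])
  mu <- stats::rlnorm(spec$n_genes, meanlog = log(spec$baseline_mean) - 0.5,
                      sdlog = 1)
  mito <- startsWith(genes, "MT-")
  if (any(mito) && spec$mito_fraction_mean > 0) {
    s_non <- sum(mu[!mito])
    mu[mito] <- s_non * spec$mito_fraction_mean /
      (1 - spec$mito_fraction_mean) / sum(mito)
  } else if (any(mito)) {
    mu[mito] <- 0
  }
  size_factor <- stats::rlnorm(length(lay$donors),
                               meanlog = -spec$donor_lib_sd^2 / 2,
                               sdlog = spec$donor_lib_sd)

  # Per (population, age) fold-change vectors over genes.
  fc_vec <- function(pop, age) {
    v <- rep(1, spec$n_genes)
    if (!is.null(pop$program)) {
      fc <- if (age == "old") pop$program$fc_old else pop$program$fc
      v[pop$program$gene] <- fc
    }
    if (age == "old" && !is.null(spec$age_effect))
      v[spec$age_effect$genes] <- v[spec$age_effect$genes] *
        spec$age_effect$old_fold
    v
  }
  fcs <- list(
    young = lapply(spec$populations, fc_vec, age = "young"),
    old = lapply(spec$populations, fc_vec, age = "old"))

  meta <- vector("list", length(lay$donors))
  blocks <- vector("list", length(lay$donors))
  for (d in seq_along(lay$donors)) {
    set.seed(seeds[d])
    age <- lay$age[d]
    n_c <- lay$n_cells[d]
    pop_idx <- sample.int(length(pop_names), n_c, replace = TRUE,
                          prob = if (age == "young") py else po)
    mu_block <- matrix(0, n_c, spec$n_genes)
    for (k in seq_along(pop_names)) {
      sel <- pop_idx == k
      if (any(sel))
        mu_block[sel, ] <- rep(mu * fcs[[age]][[k]] * size_factor[d],
                               each = sum(sel))
    }
    cnt <- stats::rnbinom(length(mu_block), size = spec$dispersion,
                          mu = mu_block)
    blocks[[d]] <- Matrix::Matrix(matrix(cnt, n_c, spec$n_genes),
                                  sparse = TRUE)
    meta[[d]] <- data.frame(
      cell = sprintf("%s_cell%05d", lay$donors[d], seq_len(n_c)),
      donor = lay$donors[d], age_group = age,
      cluster = pop_names[pop_idx], stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, meta)
  counts <- methods::as(do.call(rbind, blocks), "CsparseMatrix")
  dimnames(counts) <- list(meta$cell, genes)

  programs <- lapply(spec$populations, function(p)
    if (is.null(p$program)) character(0) else genes[p$program$gene])
  names(programs) <- pop_names
  truth <- list(
    labels = stats::setNames(meta$cluster, meta$cell),
    prob_young = stats::setNames(py, pop_names),
    prob_old = stats::setNames(po, pop_names),
    markers = programs,
    stem_program = if ("F4a" %in% pop_names) programs[["F4a"]] else character(0))
  list(counts = counts, meta = meta, truth = truth)
}

#' Generate a synthetic stem-vs-fibroblast differential-expression reference
#'
#' Emulates a published differential-expression comparison of dermal
#' fibroblasts against fibroblast-derived induced pluripotent stem cells:
#' exactly `n_up` genes are planted up in the stem state and `n_down` planted
#' down, with significant adjusted p-values; all remaining genes receive
#' small null effects and non-significant adjusted p-values. Planted genes
#' are drawn from the supplied gene namespace so downstream stemness scoring
#' is wired end-to-end; pass `up_genes` to force the planted up set to
#' contain specific genes (e.g. a population's planted stem program).
#'
#' @param genes Character vector, the cohort's gene namespace; or a single
#'   integer, auto-named via [cohort_gene_names()].
#' @param n_up,n_down Number of genes planted up/down in the stem state.
#' @param effect_size Magnitude of planted log-fold effects (> 0).
#' @param seed Seed for the draw.
#' @param up_genes,down_genes Optional genes that must be in the planted sets.
#' @param alpha Significance level separating planted from null adjusted
#'   p-values.
#' @return Data frame with one row per gene: `symbol`, `effect` (positive =
#'   up in stem cells), `p_adj`; planted sets attached as attributes
#'   `planted_up` / `planted_down`.
#' @export
generate_reference_de <- function(genes, n_up = 250, n_down = 250,
                                  effect_size = 2, seed = 1,
                                  up_genes = NULL, down_genes = NULL,
                                  alpha = 0.05) {
  if (is.numeric(genes) && length(genes) == 1L)
    genes <- cohort_gene_names(as.integer(genes))
  n_genes <- length(genes)
  if (n_up + n_down > n_genes)
    stop("n_up + n_down exceeds the number of genes")
  if (effect_size <= 0) stop("effect_size must be > 0")
  stopifnot(all(up_genes %in% genes), all(down_genes %in% genes))
  set.seed(seed)
  up <- unique(up_genes)
  if (length(up) > n_up) stop("more forced up_genes than n_up")
  pool <- setdiff(genes, c(up, down_genes))
  up <- c(up, sample(pool, n_up - length(up)))
  down <- unique(down_genes)
  if (length(down) > n_down) stop("more forced down_genes than n_down")
  pool <- setdiff(genes, c(up, down))
  down <- c(down, sample(pool, n_down - length(down)))

  effect <- stats::rnorm(n_genes, 0, 0.1)
  p_adj <- stats::runif(n_genes, alpha, 1)
  iu <- match(up, genes); idn <- match(down, genes)
  effect[iu] <- effect_size * (1 + stats::runif(n_up, 0, 0.5))
  effect[idn] <- -effect_size * (1 + stats::runif(n_down, 0, 0.5))
  p_adj[c(iu, idn)] <- stats::runif(n_up + n_down, 1e-12, alpha / 2)
  structure(
    data.frame(symbol = genes, effect = effect, p_adj = p_adj,
               stringsAsFactors = FALSE),
    planted_up = up, planted_down = down)
}
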