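---
title: "Methods: composition and stemness analysis of aging dermal fibroblasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: composition and stemness analysis of aging dermal fibroblasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific setting

Human skin harbours several transcriptionally distinct dermal fibroblast
populations. One of them, the dermal sheath (DS) that wraps the hair
follicle, contains hair follicle dermal stem cells and is of particular
interest in skin aging: in droplet scRNA-seq of whole-skin biopsies from
young and old donors, the DS population both shrinks severalfold with age
and loses its stem-cell-like expression profile. `dermalscore` implements
the quantitative analyses behind such a study as a reusable, tested
pipeline: cell-level quality control, normalisation, one-vs-rest marker
statistics, signature and dot-plot summaries, a reference-based per-cell
stemness score, and young-versus-old composition odds ratios — all
exercised end-to-end against a synthetic cohort generator with known ground
truth, because the real deposited cohorts (tens of thousands of cells) are
not a practical test substrate.

# Quality control and normalisation

Cells are filtered on three criteria, with **strict** inequalities so that
boundary cells are retained: fewer than `min_genes = 200` expressed genes
(count > 0), more than `max_genes = 7500` expressed genes, or a
mitochondrial fraction exceeding `max_mito = 0.05`. Mitochondrial genes are
recognised by the case-sensitive `MT-` symbol prefix (human HGNC
convention). Fractions are computed on UMI counts — droplet protocols count
unique molecules, not reads — and the QC report records this. An all-zero
cell is assigned mitochondrial fraction 0 (never a division error) and is
removed by the `min_genes` rule. Genes are never removed, and filtering is
idempotent.

Normalisation is the per-cell scaled log transform

$$v_{cg} = \ln\!\left(1 + \frac{x_{cg}}{\sum_g x_{cg}} \cdot s\right),
\qquad s = 10^6 \text{ by default},$$

i.e. log counts-per-million. We interpret the conventional "TPM" label for
this layer as counts-per-scale without a gene-length term, since 3'
droplet counts have no length component; `scale` is configurable. The
natural log with pseudocount 1 is used because it avoids $\log 0$, is the
dominant single-cell convention, and makes the zero pattern of the
normalised matrix identical to that of the counts. Two identities follow
and are enforced by tests: $v = 0 \iff x = 0$, and per cell
$\sum_g (e^{v_{cg}} - 1) = s$.

# Marker statistics and signatures

`find_markers()` compares one cluster against all remaining cells pooled,
gene by gene, with a two-sided unpaired Wilcoxon rank-sum test. Count data
are tie-heavy, so the normal approximation with midrank tie correction and
continuity correction is the operative path; for small tie-free inputs the
exact distribution is used, which is what lets the test suite check the
implementation against full enumeration of all two-group splits of up to
ten cells. Genes are pre-filtered to those expressed in at least
`min_pct = 0.1` of either group (standard practice; configurable). The fold
change is computed on de-logged means with pseudocount 1,

$$\mathrm{logFC} = \ln\frac{\overline{(e^{v}-1)}_{\text{in}} + 1}
{\overline{(e^{v}-1)}_{\text{out}} + 1},$$

and marker p-values are Bonferroni-adjusted over the tested genes — the
convention of the widely used cluster-marker workflow this mirrors. The
over-representation test (`enrichment_test()`), by contrast, uses
Benjamini–Hochberg across terms, which is the usual choice where dozens of
gene sets are screened; it is a plain upper-tail hypergeometric test on
user-supplied sets, deliberately agnostic of any ontology database.

A gene signature score is the per-cell mean normalised expression over the
signature's genes (missing genes are dropped and reported, order is
irrelevant), and `dotplot_summary()` reports, per cluster, the percent of
cells expressing a feature and its average expression — for signatures,
"expressed" means score > 0.

# The stemness score

The score situates each cell between a fibroblast and a stem-cell
expression state defined by an external differential-expression reference
(fibroblasts versus fibroblast-derived induced pluripotent stem cells).
From the reference, the `k = 250` most up-regulated and `k = 250` most
down-regulated significant genes (adjusted p < 0.05) are selected, ranking
by effect size; ties at the k-th rank break by ascending adjusted p, then
symbol, so selection is deterministic. Whether ranking should be by effect
or by significance is genuinely open; effect-size ranking is the default
and significance enters through the gate and the tie-break. For each cell
and each list,

$$\text{identity} = n + \sum \log \mathrm{TPM}, \qquad
\text{stemness} = \frac{\text{stem identity} + 1}
{\text{fibroblast identity} + 1},$$

where $n$ is the number of listed genes the cell expresses (raw count > 0 —
the simplest testable reading) and the cumulative term sums log expression
over the listed genes. Two readings of "cumulative expression signal of all
genes" exist; both are implemented:

* `sum_mode = "all"` (default): $\sum \ln(1 + \mathrm{CP}s)$ over **all**
  listed genes. Zero-count genes contribute 0, no $\log 0$ arises, and the
  score is monotone: raising an up-list count never lowers it, raising a
  down-list count never raises it (a tested invariant).
* `sum_mode = "expressed"`: $\sum \ln(\mathrm{CP}s)$ over **expressed**
  listed genes only. This is closer to a literal "log TPM" but admits
  negative contributions from genes below one count per scale unit.

The score is strictly positive in the default mode and equals exactly 1
when a cell expresses none of the listed genes. Group comparisons use
unpaired Wilcoxon rank-sum tests with explicit sidedness: one-sided
one-vs-rest for "which population scores highest", two-sided for
young-versus-old contrasts.

# Composition odds ratios

Each cluster is tested against all remaining cells pooled in a 2×2 table of
age group × membership. The p-value is the two-sided Fisher exact
probability (sum of all tables with point probability ≤ the observed one —
the mainstream convention; the method is checked against direct
enumeration over the hypergeometric support for tables up to n = 60). The
reported OR is the sample cross-product $ad/bc$, in an **explicit
orientation**: populations depleted with age read naturally as
"young-enriched" (OR > 1 means more likely in the young), old-expanded
populations as "old-enriched". The 95% CI is the Woolf logit interval
$\exp(\ln \mathrm{OR} \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$ with the
Haldane 0.5 correction iff any cell is zero; a conditional-MLE exact
interval is available behind `ci_method = "exact"`. We make no attempt to
reproduce any particular published CI: published intervals of this kind
are often method-unlabelled and occasionally internally inconsistent, so
the package commits to one defensible, documented method. Donor-level
replication uses `fraction_test()`: a two-tailed unpaired Student t-test
(Welch behind a flag) on per-donor cluster fractions with group means ±
SEM.

# What the synthetic cohort emulates

`synthetic_spec()` describes a cohort: 3 young and 4 old donors by default,
five populations F1–F4b whose default membership probabilities encode the
composition shifts under study (young fractions anchored at 0.300, 0.350,
0.286, 0.034, 0.030; old fractions derived so that the one-vs-rest odds
ratios are 1.685 old-enriched for F1 and 1.666, 7.097, 2.258 young-enriched
for F3, F4a, F4b, with F2 absorbing the remainder — the anchors are free
parameters because only the odds ratios, not the fractions, are fixed by
the design). Counts are negative binomial with a single cohort-wide
dispersion (`size = 2`) and log-normal gene baseline means
(`baseline_mean = 0.3` expected counts/gene/cell, sdlog 1) — the simplest
model with realistic overdispersion. Population programs multiply selected
genes' means by a fold-change, optionally attenuated in old cells, and a
global `age_effect` can scale chosen genes in all old cells; the F4a
program doubles as the planted dermal-sheath/stem program. Donor effects
are a multiplicative log-normal library-size factor only (sdlog 0.1), so
odds-ratio recovery is not confounded by donor composition noise. Thirteen
`MT-`-named genes carry 3% of each cell's counts in expectation. One master
seed drives everything; per-donor substreams are derived from it, so output
is bit-identical for identical spec + seed.

The generator intentionally does **not** emulate: doublets, ambient RNA,
batch effects beyond donor scaling, spliced/unspliced layers, or any
spatial hair-follicle structure. Passing tests therefore demonstrate the
statistical machinery on clean overdispersed counts with planted truth —
they do not certify performance on real data with those artefacts, which is
why QC and the donor-level fraction test exist as guards in the real-data
path.

`generate_reference_de()` emulates the external stem-vs-fibroblast
reference: exactly `n_up`/`n_down` genes planted with significant signed
effects in the cohort's own gene namespace (optionally forced to contain a
population's planted program), all other genes null. Rank-based selection
downstream recovers the planted sets exactly, which is the wiring the tests
rely on.

# Problem sizes and numerical choices

The test suite runs the composition parameter-recovery at the study's
study-scale group sizes (19,139 young, 31,010 old fibroblasts; 200 cohorts per
target, metadata-level simulation, ~30 s total) and the expression-level
analyses at 5,950–7,000 cells × 1,000–2,000 genes, sizes chosen to give
every population ≥ 500 cells per age group where the stemness pattern is
asserted. Null-calibration checks use 1,000 genes and 200 permutations with
a Kolmogorov–Smirnov test at α = 0.01. Exact-test oracles run at ≤ 10 cells
(rank-sum, full enumeration of splits) and table totals ≤ 60 (Fisher).
Degenerate inputs are errors, not silent answers: zero-cell matrices,
zero-total cells at normalisation, absent clusters, empty margins, empty
gene-list intersections. Gene-symbol matching is case-sensitive throughout;
mismatches are reported, never silently dropped.

# Known limitations

* The stemness score inherits the reference's gene selection; with fewer
  than `k` significant genes per direction the lists shrink (with a
  warning) and scores are not comparable across different references.
* The composition model treats cells as independent draws; donor-level
  overdispersion of composition is deliberately out of scope of the OR
  machinery (the per-donor t-test is the provided donor-level view).
* `find_markers()` is a marker screen, not a differential-abundance or
  pseudobulk DE method; p-values at this scale are anti-conservative with
  respect to donor correlation, exactly as in the workflow it mirrors.
* Clustering itself is an input: the pipeline consumes labels (or
  ground-truth synthetic labels); it never computes embeddings or graphs.
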