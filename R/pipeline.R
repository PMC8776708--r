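# End-to-end orchestration: simulate/load -> qc -> normalize -> markers ->
# stemness -> composition, with atomic result files and a machine-readable
# run report.

.write_atomic <- function(writer, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temp file onto ", path)
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  .write_atomic(function(tmp) utils::write.table(
    df, tmp, sep = "\t", quote = FALSE, row.names = FALSE), path)
}

write_json_atomic <- function(x, path) {
  .write_atomic(function(tmp) jsonlite::write_json(
    x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    force = TRUE),
    path)
}

#' Read a two-column signature file
#'
#' Tab-separated with header columns `name` and `gene`; one row per
#' (signature, gene) pair.
#' @param path File path.
#' @return Named list of gene vectors.
#' @export
read_signatures <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "gene") %in% names(df)))
  split(df$gene, df$name)
}

#' Read a stem-vs-fibroblast differential-expression reference table
#'
#' Tab-separated with header columns `symbol`, `effect`, `p_adj`.
#' @param path File path.
#' @return Data frame suitable for [select_signature_genes()].
#' @export
read_reference_de <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "effect", "p_adj") %in% names(df)))
  df
}

.validate_pipeline_config <- function(cfg) {
  has_input <- !is.null(cfg$input)
  has_syn <- !is.null(cfg$synthetic)
  if (has_input == has_syn)
    stop("config error: exactly one of 'input' and 'synthetic' must be set")
  if (has_input) {
    if (is.null(cfg$meta)) stop("config error: 'input' requires 'meta'")
    if (!dir.exists(cfg$input)) stop("config error: input directory not found")
    if (!file.exists(cfg$meta)) stop("config error: meta file not found")
  }
  if (is.null(cfg$out)) stop("config error: 'out' directory must be set")
  invisible(cfg)
}

.as_synthetic_spec <- function(x, seed) {
  if (inherits(x, "synthetic_spec")) return(x)
  args <- x[setdiff(names(x), "populations")]
  if (is.null(args$seed)) args$seed <- seed
  do.call(synthetic_spec, args)
}

#' Run the full composition/stemness pipeline
#'
#' Executes, in order: cohort simulation (or loading a 10x bundle plus cell
#' annotation), QC filtering, normalisation, one-vs-rest marker detection,
#' stemness scoring with young/old comparisons, and cluster-composition
#' analysis. All result tables are written atomically under `cfg$out`;
#' identical configuration and seed give identical outputs.
#'
#' @param cfg Configuration list, or path to a YAML file holding one.
#'   Exactly one of `synthetic` (arguments to [synthetic_spec()], or a ready
#'   spec) and `input` (10x bundle directory, with `meta` a TSV of per-cell
#'   `cell`/`donor`/`age_group`/`cluster`) must be set. Optional entries:
#'   `qc` (arguments to [qc_config()]), `scale` (normalisation scale,
#'   default 1e6), `marker_clusters` (clusters to test; default all),
#'   `signatures` (path to a signature TSV), `reference_de` (path to a
#'   reference table; default: a synthetic reference wired to the cohort's
#'   planted stem program), `k` (signature genes per direction, default
#'   250), `focal_cluster` (cluster for the per-donor fraction test; default
#'   "F4a" when present), `seed` (default 1), `out` (output directory).
#' @return The run report (also written to `out/report.json`), listing for
#'   every stage the cell/gene counts and output paths.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  .validate_pipeline_config(cfg)
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  scale <- if (is.null(cfg$scale)) 1e6 else cfg$scale
  out_dir <- cfg$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(
    package = "dermalscore",
    version = as.character(utils::packageVersion("dermalscore")),
    config = cfg[setdiff(names(cfg), "populations")],
    stages = list(), warnings = character(0))
  note <- function(stage, ...) {
    report$stages[[stage]] <<- list(...)
    message(sprintf("[%s] done", stage))
  }

  # Stage 1: simulate or load ------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$synthetic)) {
    spec <- .as_synthetic_spec(cfg$synthetic, seed)
    cohort <- generate_cohort(spec)
    counts <- cohort$counts; meta <- cohort$meta; truth <- cohort$truth
    bundle <- file.path(out_dir, "counts_10x")
    write_10x(counts, bundle)
    write_tsv_atomic(meta, file.path(out_dir, "cell_meta.tsv"))
    note("simulate", n_cells = nrow(counts), n_genes = ncol(counts),
         outputs = c(bundle, file.path(out_dir, "cell_meta.tsv")))
  } else {
    counts <- read_10x(cfg$input)
    meta <- utils::read.delim(cfg$meta, stringsAsFactors = FALSE)
    stopifnot(all(c("cell", "donor", "age_group", "cluster") %in% names(meta)))
    meta <- meta[match(rownames(counts), meta$cell), , drop = FALSE]
    if (anyNA(meta$cell)) stop("meta is missing annotation for some barcodes")
    note("load", n_cells = nrow(counts), n_genes = ncol(counts),
         inputs = c(cfg$input, cfg$meta))
  }

  # Stage 2: QC --------------------------------------------------------------
  qc_cfg <- do.call(qc_config, if (is.null(cfg$qc)) list() else cfg$qc)
  qc <- qc_filter(counts, qc_cfg, meta = meta)
  counts <- qc$counts; meta <- qc$meta
  write_json_atomic(qc$report, file.path(out_dir, "qc_report.json"))
  note("qc", n_cells = nrow(counts), n_removed = qc$report$n_removed,
       outputs = file.path(out_dir, "qc_report.json"))

  # Stage 3: normalize -------------------------------------------------------
  norm <- normalize_counts(counts, scale = scale)
  note("normalize", scale = scale, log = attr(norm, "log"))

  # Stage 4: markers (+ optional signature dot plots) ------------------------
  clusters <- if (is.null(cfg$marker_clusters)) sort(unique(meta$cluster))
    else cfg$marker_clusters
  marker_tab <- do.call(rbind, lapply(clusters, function(cl)
    cbind(cluster = cl, find_markers(norm, meta$cluster, cl))))
  write_tsv_atomic(marker_tab, file.path(out_dir, "markers.tsv"))
  outputs <- file.path(out_dir, "markers.tsv")
  if (!is.null(cfg$signatures)) {
    sigs <- read_signatures(cfg$signatures)
    dots <- dotplot_summary(norm, meta$cluster, signatures = sigs)
    write_tsv_atomic(dots, file.path(out_dir, "signature_dotplot.tsv"))
    outputs <- c(outputs, file.path(out_dir, "signature_dotplot.tsv"))
  }
  note("markers", clusters = clusters, n_tests = nrow(marker_tab),
       outputs = outputs)

  # Stage 5: stemness --------------------------------------------------------
  k <- if (is.null(cfg$k)) 250L else as.integer(cfg$k)
  ref <- if (!is.null(cfg$reference_de)) {
    read_reference_de(cfg$reference_de)
  } else if (!is.null(truth)) {
    generate_reference_de(colnames(counts), n_up = k, n_down = k,
                          seed = seed, up_genes = truth$stem_program)
  } else {
    stop("config error: 'reference_de' is required for non-synthetic input")
  }
  gl <- select_signature_genes(ref, k = k)
  sc <- stemness_score(norm, gl$up, gl$down, counts = counts)
  write_tsv_atomic(sc, file.path(out_dir, "stemness.tsv"))
  cmp <- compare_stemness(sc$score, factor(meta$age_group,
                                           levels = c("young", "old")),
                          alternative = "two.sided", level = "young")
  by_pop <- stemness_by_population(sc$score, meta$cluster)
  write_tsv_atomic(by_pop, file.path(out_dir, "stemness_by_population.tsv"))
  note("stemness", n_up = length(gl$up), n_down = length(gl$down),
       young_vs_old_p = cmp$p.value,
       outputs = file.path(out_dir, c("stemness.tsv",
                                      "stemness_by_population.tsv")))

  # Stage 6: composition -----------------------------------------------------
  comp <- composition_analysis(meta)
  write_tsv_atomic(comp, file.path(out_dir, "composition.tsv"))
  focal <- cfg$focal_cluster
  if (is.null(focal) && "F4a" %in% meta$cluster) focal <- "F4a"
  frac_p <- NULL
  if (!is.null(focal)) {
    fr <- donor_fractions(meta, focal)
    if (all(table(fr$age_group) >= 2)) {
      ft <- fraction_test(fr$fraction, fr$age_group)
      frac_p <- ft$p.value
      write_tsv_atomic(fr, file.path(out_dir, "donor_fractions.tsv"))
    }
  }
  note("composition", n_clusters = nrow(comp), focal_cluster = focal,
       fraction_test_p = frac_p,
       outputs = file.path(out_dir, "composition.tsv"))

  write_json_atomic(report, file.path(out_dir, "report.json"))
  invisible(report)
}
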