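#!/usr/bin/env Rscript
# Stage 3: one-vs-rest marker detection and dermal-sheath signature summary.
#
# Wilcoxon rank-sum markers for every population against the rest
# (Bonferroni-adjusted), then a dot-plot summary (percent expressed, average
# expression) of the planted dermal-sheath program across populations.

suppressPackageStartupMessages({library(Matrix); library(dermalscore)})

dat <- readRDS("scratch/normalized.rds")
cohort <- readRDS("scratch/cohort.rds")

markers <- do.call(rbind, lapply(sort(unique(dat$meta$cluster)), function(cl)
  cbind(cluster = cl, find_markers(dat$norm, dat$meta$cluster, cl))))
write.table(markers, "scratch/03_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

top <- do.call(rbind, lapply(split(markers, markers$cluster), function(m)
  head(m[m$logFC > 0, c("cluster", "gene", "logFC", "p_adj",
                        "pct_in", "pct_out")], 5)))
write.table(top, "results/03_top_markers.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("top marker per population:")
print(do.call(rbind, lapply(split(top, top$cluster), head, 1)),
      row.names = FALSE)

planted <- cohort$truth$markers
hits <- vapply(names(planted), function(cl) {
  m <- markers[markers$cluster == cl & markers$p_adj < 0.05 & markers$logFC > 0, ]
  mean(planted[[cl]] %in% m$gene)
}, numeric(1))
message("fraction of planted markers recovered (p_adj < 0.05, logFC > 0):")
print(round(hits, 3))

ds_sig <- head(planted$F4a, 10)  # ten strongest planted dermal-sheath genes
dots <- dotplot_summary(dat$norm, dat$meta$cluster,
                        signatures = list(DS_signature = ds_sig))
write.table(dots, "results/03_ds_signature_dotplot.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("dermal-sheath signature average expression by population:")
print(dots[order(-dots$avg_expression), ], row.names = FALSE)
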