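#!/usr/bin/env Rscript
# Stage 5: which reference genes are spatially informative? Computes
# per-gene binary entropy and the join-count autocorrelation Z over the
# atlas, the transcriptomic statistics over the cells, their
# cross-correlation table, and a one-sided shift test comparing
# frequently selected genes against the rest.

suppressPackageStartupMessages(library(crowdmap))

data_dir <- "results/data"
ref <- read_spatial_reference(file.path(data_dir, "atlas.tsv"),
                              file.path(data_dir, "geometry.tsv"))
expr <- read_expression(file.path(data_dir, "expression_raw.tsv"), "raw")
expr <- normalize_expression(expr)
expr <- binarize_expression(expr, 0.1)

w <- knn_connectivity(ref$geometry, 10)
spatial <- atlas_spatial_stats(ref$atlas, w)
trans <- transcriptomic_gene_stats(expr)
cat(sprintf("genes with negative Z (spatially clustered): %d of %d\n",
            sum(spatial$Z < 0, na.rm = TRUE), nrow(spatial)))

ct <- correlate_stats(trans, spatial)
cat("correlation of transcriptomic vs spatial gene properties:\n")
print(round(ct, 2))

# panels picked by the baseline selectors over CV folds stand in for
# the teams' selections
folds <- assign_folds(expr$cells, 10, seed = 20240950L)
panels <- list()
for (crit in c("variance", "binarized_entropy", "expression_level")) {
  for (f in 1:10) {
    panels[[paste(crit, f)]] <-
      baseline_gene_selector(expr, 20, crit,
                             cells = folds$cell[folds$fold != f])
  }
}
freq <- selection_frequency(panels, universe = expr$genes)
sel <- woc_gene_panel(freq, 20)
for (metric in c("H", "Z")) {
  x <- spatial[[metric]][spatial$gene %in% sel]
  y <- spatial[[metric]][!spatial$gene %in% sel]
  dir <- if (metric == "H") "greater" else "less"
  st <- shift_test(x[is.finite(x)], y[is.finite(y)], dir)
  cat(sprintf("shift test, selected vs unselected, %s (%s): p = %.2g\n",
              metric, dir, st$p))
}

merged <- merge(spatial, trans, by = "gene")
write.table(merged, "results/gene_properties.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(stat = rownames(ct), ct),
            "results/property_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(freq, "results/selection_frequency.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("wrote results/gene_properties.tsv and friends\n")
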