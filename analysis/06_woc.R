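#!/usr/bin/env Rscript
# Stage 6: wisdom of the crowds. Aggregates the graded team ensemble
# into a k-means location consensus, compares it to the individual
# teams, and validates a frequency-selected gene panel against random
# panels.

suppressPackageStartupMessages(library(crowdmap))

seed <- 20240960L
data_dir <- "results/data"
ref <- read_spatial_reference(file.path(data_dir, "atlas.tsv"),
                              file.path(data_dir, "geometry.tsv"))
expr <- read_expression(file.path(data_dir, "expression_binarized.tsv"),
                        "binarized")
silver <- build_silver_standard(expr, ref$atlas, ref$geometry)

corruption <- c(a = 0.1, b = 0.2, c = 0.3, d = 0.4, e = 1)
teams <- lapply(seq_along(corruption), function(i) {
  generate_team_ensemble(silver, ref$geometry, 1,
                         corruption = corruption[i],
                         seed = seed + i)[[1]]
})
names(teams) <- names(corruption)

cons <- woc_predictions(teams, ref$geometry,
                        consensus_config(seed = seed))
rows <- lapply(c(as.list(names(teams)), list("WOC")), function(nm) {
  pred <- if (identical(nm, "WOC")) cons else teams[[nm]]
  sc <- score_submission(pred, silver, ref$atlas, expr, ref$geometry)
  data.frame(predictor = nm, s1 = sc$s1, s2 = sc$s2, s3 = sc$s3)
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE, digits = 3)
cat(sprintf("WOC s2 vs best individual: %.3f vs %.3f\n",
            tab$s2[tab$predictor == "WOC"],
            max(tab$s2[tab$predictor != "WOC"])))

pv <- panel_validation_experiment(seed = seed)
cat(sprintf(paste0("clustered 20-gene panel percentile vs 100 random",
                   " panels: s1 %.0f, s2 %.0f, s3 %.0f\n"),
            pv$percentile[["s1"]], pv$percentile[["s2"]],
            pv$percentile[["s3"]]))

write.table(tab, "results/woc_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_score_report(list(percentile = as.list(pv$percentile)),
                   "results/panel_validation.json")
cat("wrote results/woc_scores.tsv, results/panel_validation.json\n")
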