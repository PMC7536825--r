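#!/usr/bin/env Rscript
# Stage 4: simulate an ensemble of teams of graded quality around the
# silver standard, score each with the three challenge metrics, and
# rank them by bootstrap resampling with Bayes factors.

suppressPackageStartupMessages(library(crowdmap))

seed <- 20240940L
data_dir <- "results/data"
ref <- read_spatial_reference(file.path(data_dir, "atlas.tsv"),
                              file.path(data_dir, "geometry.tsv"))
expr <- read_expression(file.path(data_dir, "expression_binarized.tsv"),
                        "binarized")
silver <- build_silver_standard(expr, ref$atlas, ref$geometry)

corruption <- c(exact = 0, good = 0.1, fair = 0.3, poor = 0.6, noise = 1)
teams <- lapply(seq_along(corruption), function(i) {
  generate_team_ensemble(silver, ref$geometry, 1,
                         corruption = corruption[i],
                         seed = seed + i)[[1]]
})
names(teams) <- names(corruption)

scores <- do.call(rbind, lapply(names(teams), function(nm) {
  sc <- score_submission(teams[[nm]], silver, ref$atlas, expr,
                         ref$geometry)
  data.frame(team = nm, corruption = corruption[[nm]],
             s1 = sc$s1, s2 = sc$s2, s3 = sc$s3,
             n = sc$n_cells_scored)
}))
print(scores, row.names = FALSE, digits = 3)

rk <- bootstrap_rank(teams, silver, ref$atlas, expr, ref$geometry,
                     n_boot = 1000, seed = seed)
cat("mean bootstrap ranks (lower is better):\n")
print(round(sort(rk$mean_rank), 2))
cat(sprintf("Bayes factor exact vs good: %.2f (>= 3 reads as significant)\n",
            rk$bayes_factors["exact", "good"]))

dir.create("results", showWarnings = FALSE)
write.table(scores, "results/team_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_score_report(list(mean_rank = as.list(rk$mean_rank),
                        bayes_factors = rk$bayes_factors),
                   "results/team_ranking.json")
cat("wrote results/team_scores.tsv, results/team_ranking.json\n")
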