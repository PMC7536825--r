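#!/usr/bin/env Rscript
# Stage 7: the 10-fold cross-validation benchmark. Five baseline gene
# selectors pick panels on training cells only; held-out cells are
# mapped and scored against the silver standard; selectors are ranked
# by 100 bootstrap replicates, and a WOC consensus of all selectors is
# scored alongside.

suppressPackageStartupMessages(library(crowdmap))

report <- run_cv_benchmark(default_cv_config(seed = 20240970L),
                           out_dir = "results/cv")

cat("per-selector scores (mean over 10 folds, SD in parentheses):\n")
s <- report$summary
for (i in seq_len(nrow(s))) {
  cat(sprintf("  %-24s s1 %.2f (%.2f)  s2 %.2f (%.2f)  s3 %.2f (%.2f)\n",
              s$selector[i], s$mean_s1[i], s$sd_s1[i],
              s$mean_s2[i], s$sd_s2[i], s$mean_s3[i], s$sd_s3[i]))
}
cat("fold-to-fold panel stability (Jaccard, vs random expectation):\n")
st <- report$stability
for (i in seq_len(nrow(st))) {
  cat(sprintf("  %-24s %.2f (random: %.2f)\n", st$selector[i],
              st$mean_jaccard[i], st$expected_random[i]))
}
cat("mean bootstrap rank (100 replicates, lower is better):\n")
print(round(sort(report$ranking$mean_rank), 2))
cat(sprintf("WOC consensus: s1 %.2f, s2 %.2f, s3 %.2f\n",
            report$woc_scores$s1, report$woc_scores$s2,
            report$woc_scores$s3))
cat("wrote results/cv/\n")
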