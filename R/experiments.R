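# Canned synthetic experiments: the study conditions used by the
# analysis scripts and the acceptance checks, encapsulated once so both
# run the same computation.

#' Parameter-recovery experiment
#'
#' Generates the standard synthetic embryo (500 bins, 60 genes of which
#' 15 are spatially random decoys, 300 cells), maps cells back with the
#' full panel using the latent ON/OFF profiles (the noiseless layer;
#' profile noise enters through `flip_prob`), and reports top-1 and
#' top-10 recovery of the true bins per flip level, averaged over
#' `n_seeds` generator seeds.
#'
#' @param flip_probs profile flip probabilities to sweep.
#' @param n_seeds generator seeds per flip level.
#' @param n_bins,n_genes,n_random_genes,n_cells problem size.
#' @param seed master seed.
#' @return Data frame: `flip_prob`, `top1`, `top10` (mean rates over
#'   seeds).
#' @export
recovery_experiment <- function(flip_probs = c(0, 0.1, 0.3),
                                n_seeds = 5L, n_bins = 500L,
                                n_genes = 60L, n_random_genes = 15L,
                                n_cells = 300L, seed = 1L) {
  seeds <- derive_seeds(seed, 2L + n_seeds)
  geometry <- generate_geometry(n_bins, seed = seeds[1])
  atlas <- generate_atlas(geometry,
                          default_pattern_panel(n_genes, n_random_genes),
                          seed = seeds[2])
  rows <- lapply(flip_probs, function(fp) {
    rates <- vapply(seq_len(n_seeds), function(i) {
      truth <- synthetic_truth(flip_prob = fp, seed = seeds[2L + i])
      sim <- generate_cells(atlas, geometry, n_cells, truth)
      pred <- map_cells(sim$expr, atlas, layer = "latent")
      true_bin <- sim$truth$true_bin_per_cell
      c(top1 = mean(pred$bins[, 1] == true_bin),
        top10 = mean(vapply(seq_along(true_bin), function(ci) {
          true_bin[ci] %in% pred$bins[ci, ]
        }, logical(1))))
    }, numeric(2))
    data.frame(flip_prob = fp, top1 = mean(rates["top1", ]),
               top10 = mean(rates["top10", ]))
  })
  do.call(rbind, rows)
}

#' Wisdom-of-crowds ensemble experiment
#'
#' Builds a synthetic silver standard, an ensemble of `n_good`
#' uncorrupted teams plus `n_bad` fully corrupted teams, forms the WOC
#' consensus and compares its s2 to the individual teams' s2, per seed.
#'
#' @param n_good,n_bad team counts.
#' @param n_seeds number of replicate runs.
#' @param n_bins,n_genes,n_cells problem size.
#' @param flip_prob profile noise of the synthetic cells.
#' @param seed master seed.
#' @return Data frame per seed: `woc_s2`, `median_team_s2`,
#'   `best_team_s2`.
#' @export
woc_ensemble_experiment <- function(n_good = 4L, n_bad = 1L,
                                    n_seeds = 5L, n_bins = 300L,
                                    n_genes = 40L, n_cells = 120L,
                                    flip_prob = 0.05, seed = 1L) {
  seeds <- derive_seeds(seed, n_seeds)
  rows <- lapply(seq_len(n_seeds), function(i) {
    ss <- derive_seeds(seeds[i], 5L)
    geometry <- generate_geometry(n_bins, seed = ss[1])
    atlas <- generate_atlas(geometry, default_pattern_panel(n_genes, 5L),
                            seed = ss[2])
    sim <- generate_cells(atlas, geometry, n_cells,
                          synthetic_truth(flip_prob = flip_prob,
                                          seed = ss[3]))
    silver <- build_silver_standard(sim$expr, atlas, geometry,
                                    layer = "latent")
    teams <- c(
      generate_team_ensemble(silver, geometry, n_good, corruption = 0,
                             seed = ss[4]),
      generate_team_ensemble(silver, geometry, n_bad, corruption = 1,
                             seed = ss[5])
    )
    names(teams) <- paste0("team", seq_along(teams))
    team_s2 <- vapply(teams, score_s2, numeric(1),
                      silver = silver, geometry = geometry)
    cons <- woc_predictions(teams, geometry,
                            consensus_config(seed = seeds[i]))
    data.frame(seed = seeds[i],
               woc_s2 = score_s2(cons, silver, geometry),
               median_team_s2 = stats::median(team_s2),
               best_team_s2 = max(team_s2))
  })
  do.call(rbind, rows)
}

#' Gene-panel validation experiment
#'
#' Builds a synthetic universe of 20 spatially clustered genes padded
#' with 60 random-pattern decoys, scores the clustered 20-gene panel
#' against 100 random panels of the same size, and reports the
#' percentile per metric.
#'
#' @param n_clustered,n_random gene counts (panel = the clustered ones).
#' @param n_bins,n_cells problem size.
#' @param flip_prob profile noise.
#' @param n_null random panels.
#' @param seed master seed.
#' @return Result of [validate_panel_against_null()] plus the `panel`.
#' @export
panel_validation_experiment <- function(n_clustered = 20L,
                                        n_random = 60L, n_bins = 400L,
                                        n_cells = 150L, flip_prob = 0.1,
                                        n_null = 100L, seed = 13L) {
  ss <- derive_seeds(seed, 4L)
  geometry <- generate_geometry(n_bins, seed = ss[1])
  kinds <- c("patch", "stripe", "gradient")
  axes <- c("x", "y", "z")
  specs <- c(
    lapply(seq_len(n_clustered), function(i) {
      pattern_spec(kinds[(i - 1L) %% 3L + 1L],
                   axis = axes[(i - 1L) %% 3L + 1L],
                   on_fraction = 0.25 + 0.05 * ((i - 1L) %% 4L),
                   n_units = (i - 1L) %% 3L + 2L)
    }),
    # uninformative decoys: spatially random AND low-entropy (rare or
    # near-ubiquitous), the profile of genes that carry little location
    # information
    lapply(seq_len(n_random), function(i) {
      pattern_spec("random",
                   on_fraction = c(0.03, 0.06, 0.9, 0.95)[(i - 1L) %% 4L + 1L])
    })
  )
  atlas <- generate_atlas(geometry, specs, seed = ss[2])
  panel <- atlas$genes[seq_len(n_clustered)]
  sim <- generate_cells(atlas, geometry, n_cells,
                        synthetic_truth(flip_prob = flip_prob,
                                        seed = ss[3]))
  silver <- build_silver_standard(sim$expr, atlas, geometry,
                                  layer = "latent")
  res <- validate_panel_against_null(panel, atlas, sim$expr, silver,
                                     geometry, n_null = n_null,
                                     seed = ss[4], layer = "latent")
  c(res, list(panel = panel))
}

#' Type-I error of the one-sided shift test
#'
#' Draws both groups from the same normal distribution `n_reps` times
#' and reports the rejection rate at level `alpha`.
#'
#' @param n_reps repetitions (default 1000).
#' @param n1,n2 group sizes.
#' @param alpha nominal level.
#' @param seed integer seed.
#' @return The empirical rejection rate.
#' @export
shift_test_type1 <- function(n_reps = 1000L, n1 = 30L, n2 = 50L,
                             alpha = 0.05, seed = 9L) {
  with_seed(seed, {
    mean(vapply(seq_len(n_reps), function(i) {
      shift_test(stats::rnorm(n1), stats::rnorm(n2), "greater")$p < alpha
    }, logical(1)))
  })
}
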