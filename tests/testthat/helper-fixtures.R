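# Shared synthetic fixtures, built once per test run.

fixture_cache <- new.env(parent = emptyenv())

# A small clean world: 200 bins, 30 genes (5 random), 100 noiseless
# cells whose latent layer equals their bin's atlas row.
small_world <- function() {
  if (!is.null(fixture_cache$small)) return(fixture_cache$small)
  geometry <- generate_geometry(200, seed = 101)
  atlas <- generate_atlas(geometry, default_pattern_panel(30, 8),
                          seed = 102)
  sim <- generate_cells(atlas, geometry, 100,
                        synthetic_truth(flip_prob = 0, seed = 103))
  expr <- binarize_expression(normalize_expression(sim$expr), 0.1)
  silver <- build_silver_standard(expr, atlas, geometry, layer = "latent")
  fixture_cache$small <- list(geometry = geometry, atlas = atlas,
                              expr = expr, truth = sim$truth,
                              silver = silver)
  fixture_cache$small
}

# A noisy world with an ensemble of teams of varying corruption.
noisy_world <- function() {
  if (!is.null(fixture_cache$noisy)) return(fixture_cache$noisy)
  geometry <- generate_geometry(150, seed = 201)
  atlas <- generate_atlas(geometry, default_pattern_panel(24, 4),
                          seed = 202)
  sim <- generate_cells(atlas, geometry, 60,
                        synthetic_truth(flip_prob = 0.05, seed = 203))
  expr <- binarize_expression(normalize_expression(sim$expr), 0.1)
  silver <- build_silver_standard(expr, atlas, geometry, layer = "latent")
  teams <- list(
    clean = generate_team_ensemble(silver, geometry, 1, corruption = 0,
                                   seed = 204)[[1]],
    mild = generate_team_ensemble(silver, geometry, 1, corruption = 0.2,
                                  seed = 205)[[1]],
    heavy = generate_team_ensemble(silver, geometry, 1, corruption = 1,
                                   seed = 206)[[1]]
  )
  fixture_cache$noisy <- list(geometry = geometry, atlas = atlas,
                              expr = sim$expr, silver = silver,
                              teams = teams)
  fixture_cache$noisy
}

# Random tiny scoring instance (<= 10 cells, <= 20 bins, <= 6 genes)
# guaranteed to be scoreable: non-constant profiles, positive d_K,
# non-degenerate s3 panel.
random_toy_instance <- function(seed) {
  withr::with_seed(seed, {
    repeat {
      nb <- sample(12:20, 1)
      ng <- sample(4:6, 1)
      nc <- sample(5:10, 1)
      coords <- matrix(stats::runif(nb * 3, 0, 4), nb, 3)
      f <- matrix(stats::rbinom(nb * ng, 1, 0.5), nb, ng)
      if (any(duplicated(f)) || any(colSums(f) %in% c(0, nb))) next
      geometry <- embryo_geometry(coords, k_neighbors = 3L)
      atlas <- insitu_atlas(f, genes = sprintf("g%02d", seq_len(ng)))
      true_bin <- sample.int(nb, nc, replace = TRUE)
      noise <- matrix(stats::rbinom(ng * nc, 1, 0.1), ng, nc)
      latent <- (t(f[true_bin, , drop = FALSE]) + noise) %% 2
      expr <- expression_matrix(
        raw = matrix(1L, ng, nc), binarized = latent,
        genes = atlas$genes, cells = sprintf("c%02d", seq_len(nc)))
      silver <- build_silver_standard(expr, atlas, geometry)
      if (all(silver$ambiguous)) next
      pred_bins <- t(vapply(seq_len(nc), function(i) {
        sample.int(nb, 10)
      }, integer(10)))
      pred <- location_prediction(pred_bins, cells = expr$cells,
                                  gene_panel = atlas$genes)
      cells <- silver$cells[!silver$ambiguous]
      tmat <- expr$binarized[atlas$genes, cells, drop = FALSE]
      m <- vapply(seq_len(ng), function(s) {
        oracle_mcc(tmat[s, ],
                   atlas$f[silver$epsilon[!silver$ambiguous], s])
      }, numeric(1))
      if (sum(m) == 0) next
      return(list(geometry = geometry, atlas = atlas, expr = expr,
                  silver = silver, prediction = pred))
    }
  })
}
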