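# Hand-buildable silver standard for constructed-geometry score checks.
manual_silver <- function(cells, epsilon, reference_list, d84_ref,
                          ambiguous = rep(FALSE, length(cells)),
                          gene_panel = NULL) {
  structure(list(cells = cells, epsilon = epsilon,
                 reference_list = reference_list, d84_ref = d84_ref,
                 ambiguous = ambiguous, gene_panel = gene_panel),
            class = "silver_standard")
}

test_that("weights follow the inverse-distance construction", {
  # truth at the origin; 10 predicted bins all at distance 2; d84 = 1
  coords <- rbind(c(0, 0, 0),
                  t(vapply(1:10, function(i) {
                    ang <- 2 * pi * i / 10
                    c(2 * cos(ang), 2 * sin(ang), 0)
                  }, numeric(3))),
                  c(5, 5, 5))
  geometry <- embryo_geometry(coords, k_neighbors = 3)
  silver <- manual_silver("c1", 1L,
                          matrix(2:11, 1, dimnames = list("c1")), 1)
  pred <- location_prediction(matrix(2:11, 1, dimnames = list("c1")))
  w <- location_weights(pred, silver, geometry)
  expect_equal(w$d_K, 2)
  expect_equal(w$p_K, 0.5)
})

test_that("the reference list is the fixed point of the weights", {
  world <- small_world()
  ref <- location_prediction(world$silver$reference_list,
                             cells = world$silver$cells,
                             gene_panel = world$atlas$genes)
  w <- location_weights(ref, world$silver, world$geometry)
  expect_equal(w$d_K, world$silver$d84_ref, tolerance = 1e-12)
  expect_equal(w$p_K, rep(1, length(world$silver$cells)),
               tolerance = 1e-12)
})

test_that("a perfect submission scores (1, 1, 1)", {
  world <- small_world()
  ref <- location_prediction(world$silver$reference_list,
                             cells = world$silver$cells,
                             gene_panel = world$atlas$genes)
  sc <- score_submission(ref, world$silver, world$atlas, world$expr,
                         world$geometry, layer = "latent")
  expect_equal(sc$s1, 1, tolerance = 1e-12)
  expect_equal(sc$s2, 1, tolerance = 1e-12)
  expect_equal(sc$s3, 1, tolerance = 1e-12)
  expect_equal(sc$n_cells_scored, length(world$silver$cells))
})

test_that("doubling all predicted distances halves s2", {
  # truth at origin; reference ring at distance 1, prediction ring at 2
  ring <- function(r) t(vapply(1:10, function(i) {
    ang <- 2 * pi * i / 10
    c(r * cos(ang), r * sin(ang), 0)
  }, numeric(3)))
  coords <- rbind(c(0, 0, 0), ring(1), ring(2))
  geometry <- embryo_geometry(coords, k_neighbors = 3)
  silver <- manual_silver("c1", 1L,
                          matrix(2:11, 1, dimnames = list("c1")), 1)
  pred <- location_prediction(matrix(12:21, 1, dimnames = list("c1")))
  expect_equal(score_s2(pred, silver, geometry), 0.5)
})

test_that("single-cell s1 reduces to the profile MCC", {
  world <- small_world()
  keep <- world$silver$cells[1]
  one <- manual_silver(keep, world$silver$epsilon[1],
                       world$silver$reference_list[1, , drop = FALSE],
                       world$silver$d84_ref[1])
  wrong_top <- world$silver$reference_list[1, c(2, 1, 3:10), drop = FALSE]
  rownames(wrong_top) <- keep
  pred <- location_prediction(wrong_top, gene_panel = world$atlas$genes)
  expect_equal(score_s1(pred, one, world$atlas, world$geometry),
               mcc(world$atlas$f[wrong_top[1], ],
                   world$atlas$f[world$silver$epsilon[1], ]))
})

test_that("s3 reduces to the self-consistency identity when top-1 is exact", {
  toy <- random_toy_instance(23)
  keep <- !toy$silver$ambiguous
  # prediction whose top-1 equals the ground truth but random tail
  bins <- toy$silver$reference_list
  pred <- location_prediction(bins, cells = toy$silver$cells,
                              gene_panel = toy$atlas$genes)
  cells <- toy$silver$cells[keep]
  tmat <- toy$expr$binarized[toy$atlas$genes, cells, drop = FALSE]
  m <- vapply(seq_along(toy$atlas$genes), function(s) {
    oracle_mcc(tmat[s, ], toy$atlas$f[toy$silver$epsilon[keep], s])
  }, numeric(1))
  expect_equal(score_s3(pred, toy$silver, toy$atlas, toy$expr),
               sum(m^2) / sum(m), tolerance = 1e-12)
})

test_that("scores equal the straight-from-the-formulas oracle on random toys", {
  for (seed in 1:50) {
    toy <- random_toy_instance(seed)
    got <- score_submission(toy$prediction, toy$silver, toy$atlas,
                            toy$expr, toy$geometry)
    want <- oracle_scores(toy$prediction, toy$silver, toy$atlas,
                          toy$expr, toy$geometry)
    expect_equal(got$s1, want$s1, tolerance = 1e-12)
    expect_equal(got$s2, want$s2, tolerance = 1e-12)
    expect_equal(got$s3, want$s3, tolerance = 1e-12)
  }
})

test_that("scores are invariant to permuting cell order", {
  toy <- random_toy_instance(31)
  base <- score_submission(toy$prediction, toy$silver, toy$atlas,
                           toy$expr, toy$geometry)
  perm <- withr::with_seed(1, sample(seq_along(toy$silver$cells)))
  silver_p <- manual_silver(toy$silver$cells[perm],
                            toy$silver$epsilon[perm],
                            toy$silver$reference_list[perm, , drop = FALSE],
                            toy$silver$d84_ref[perm],
                            toy$silver$ambiguous[perm])
  got <- score_submission(toy$prediction, silver_p, toy$atlas,
                          toy$expr, toy$geometry)
  expect_equal(got$s1, base$s1, tolerance = 1e-12)
  expect_equal(got$s2, base$s2, tolerance = 1e-12)
  expect_equal(got$s3, base$s3, tolerance = 1e-12)
})

test_that("ambiguous cells are dropped from the scored count", {
  toy <- random_toy_instance(37)
  amb <- toy$silver$ambiguous
  amb[1:3] <- TRUE
  silver2 <- manual_silver(toy$silver$cells, toy$silver$epsilon,
                           toy$silver$reference_list, toy$silver$d84_ref,
                           amb)
  sc <- score_submission(toy$prediction, silver2, toy$atlas, toy$expr,
                         toy$geometry)
  expect_equal(sc$n_cells_scored, sum(!amb))
  all_amb <- manual_silver(toy$silver$cells, toy$silver$epsilon,
                           toy$silver$reference_list, toy$silver$d84_ref,
                           rep(TRUE, length(amb)))
  expect_error(score_s2(toy$prediction, all_amb, toy$geometry),
               "no non-ambiguous")
})

test_that("missing cells abort scoring instead of being dropped", {
  world <- noisy_world()
  short <- location_prediction(
    world$teams$clean$bins[-1, , drop = FALSE],
    cells = world$silver$cells[-1],
    gene_panel = world$atlas$genes)
  expect_error(score_s2(short, world$silver, world$geometry), "missing")
})

test_that("bayes factors follow the win-count conventions", {
  expect_equal(bayes_factor(c(rep(1, 750), rep(2, 250)),
                            c(rep(2, 750), rep(1, 250))), 3)
  expect_equal(bayes_factor(rep(1, 10), rep(2, 10)), Inf)
  expect_equal(bayes_factor(rep(1.5, 10), rep(1.5, 10)), 1)
  expect_error(bayes_factor(1:3, 1:4), "length")
})

test_that("bootstrap ranking is seeded, paired and favors the clean team", {
  world <- noisy_world()
  subs <- list(clean = world$teams$clean, heavy = world$teams$heavy)
  r1 <- bootstrap_rank(subs, world$silver, world$atlas, world$expr,
                       world$geometry, n_boot = 200, seed = 5,
                       layer = "latent")
  r2 <- bootstrap_rank(subs, world$silver, world$atlas, world$expr,
                       world$geometry, n_boot = 200, seed = 5,
                       layer = "latent")
  expect_identical(r1$ranks, r2$ranks)
  expect_lt(r1$mean_rank["clean"], r1$mean_rank["heavy"])
  # reciprocal Bayes factors multiply to 1 when no replicate ties
  no_tie <- r1$ranks["clean", ] != r1$ranks["heavy", ]
  bf <- r1$bayes_factors["clean", "heavy"]
  if (all(no_tie) && is.finite(bf) && bf > 0) {
    expect_equal(bf * r1$bayes_factors["heavy", "clean"], 1)
  } else if (all(no_tie)) {
    # one-sided sweep: the reciprocal pair is (Inf, 0)
    expect_true(bf %in% c(0, Inf))
  }
  expect_error(bootstrap_rank(subs, world$silver, world$atlas,
                              world$expr, world$geometry, n_boot = 0),
               "n_boot")
  expect_error(bootstrap_rank(subs["clean"], world$silver, world$atlas,
                              world$expr, world$geometry),
               "two teams")
})

test_that("identical submissions tie with Bayes factor 1", {
  world <- noisy_world()
  subs <- list(a = world$teams$mild, b = world$teams$mild)
  r <- bootstrap_rank(subs, world$silver, world$atlas, world$expr,
                      world$geometry, n_boot = 50, seed = 2,
                      layer = "latent")
  expect_equal(r$ranks["a", ], r$ranks["b", ])
  expect_equal(r$bayes_factors["a", "b"], 1)
})
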