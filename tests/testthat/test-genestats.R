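test_that("binary entropy identities and symmetry", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.25), 0.8112781244591328, tolerance = 1e-9)
  p <- seq(0, 1, by = 0.05)
  expect_equal(binary_entropy(p), binary_entropy(1 - p))
  expect_error(binary_entropy(1.1), "0, 1")
})

test_that("knn connectivity rows sum to k and respect the tie rule", {
  geo <- embryo_geometry(cbind(c(0, 1, 2), 0, 0), k_neighbors = 1)
  w <- knn_connectivity(geo, 1)
  expect_equal(unname(as.matrix(w$w)[2, ]), c(1, 0, 0))
  geo2 <- generate_geometry(60, seed = 3)
  w2 <- knn_connectivity(geo2, 10)
  expect_equal(unname(Matrix::rowSums(w2$w)), rep(10, 60))
  expect_true(all(Matrix::diag(w2$w) == 0))
})

ring_geometry <- function(n = 6) {
  ang <- 2 * pi * seq_len(n) / n
  embryo_geometry(cbind(cos(ang), sin(ang), 0), k_neighbors = 2)
}

test_that("ring connectivity equals the cycle-graph adjacency", {
  geo <- ring_geometry()
  w <- as.matrix(knn_connectivity(geo, 2)$w)
  adj <- matrix(0, 6, 6)
  for (i in 1:6) {
    adj[i, c((i %% 6) + 1, ((i - 2) %% 6) + 1)] <- 1
  }
  expect_equal(unname(w), adj)
  expect_true(isSymmetric(w))
})

test_that("join counts on the 6-ring match exhaustive edge enumeration", {
  geo <- ring_geometry()
  w <- knn_connectivity(geo, 2)
  alternating <- c(1, 0, 1, 0, 1, 0)
  blocked <- c(1, 1, 1, 0, 0, 0)
  jc_alt <- join_count_z(alternating, w)
  jc_blk <- join_count_z(blocked, w)
  expect_equal(jc_alt$bw_obs, 6)
  expect_equal(jc_blk$bw_obs, 2)
  expect_gt(jc_alt$z, 0)   # dispersion
  expect_lt(jc_blk$z, 0)   # clustering
})

test_that("closed-form null moments match the permutation oracle", {
  withr::with_seed(8, {
    for (rep in 1:3) {
      coords <- matrix(runif(90), 30, 3)
      geo <- embryo_geometry(coords, k_neighbors = 4)
      w <- knn_connectivity(geo, 4)
      gene <- numeric(30)
      gene[sample.int(30, sample(8:15, 1))] <- 1
      jc <- join_count_z(gene, w)
      null_bw <- oracle_permutation_null(gene, as.matrix(w$w),
                                         20000, seed = rep)
      se_mean <- sd(null_bw) / sqrt(length(null_bw))
      expect_lt(abs(jc$e_bw - mean(null_bw)), 3 * se_mean)
      # variance of a sample variance: ~ var * sqrt(2/(n-1)) for
      # near-normal BW; allow 3 of those
      se_var <- var(null_bw) * sqrt(2 / (length(null_bw) - 1))
      expect_lt(abs(jc$var_bw - var(null_bw)), 3 * se_var)
    }
  })
})

test_that("constant patterns yield an undefined Z with a warning", {
  geo <- ring_geometry()
  w <- knn_connectivity(geo, 2)
  expect_warning(jc <- join_count_z(rep(1, 6), w), "constant")
  expect_equal(jc$bw_obs, 0)
  expect_true(is.nan(jc$z))
  expect_error(join_count_z(c(1, 0), w), "length")
})

test_that("Z is invariant to relabeling ON and OFF", {
  withr::with_seed(21, {
    geo <- generate_geometry(80, seed = 22)
    w <- knn_connectivity(geo, 10)
    for (i in 1:10) {
      g <- rbinom(80, 1, runif(1, 0.2, 0.8))
      if (all(g == g[1])) next
      a <- join_count_z(g, w)
      b <- join_count_z(1 - g, w)
      expect_equal(a$z, b$z, tolerance = 1e-12)
    }
  })
})

test_that("Z is invariant under rigid rotation of the geometry", {
  geo <- generate_geometry(70, seed = 23)
  theta <- 0.7
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  geo_rot <- embryo_geometry(geo$coords %*% rot, k_neighbors = 10)
  w1 <- knn_connectivity(geo, 10)
  w2 <- knn_connectivity(geo_rot, 10)
  g <- withr::with_seed(3, rbinom(70, 1, 0.4))
  expect_equal(join_count_z(g, w1)$z, join_count_z(g, w2)$z,
               tolerance = 1e-9)
})

test_that("structured patterns are more clustered than random ones", {
  deltas <- vapply(1:20, function(i) {
    geo <- generate_geometry(250, seed = 500 + i)
    w <- knn_connectivity(geo, 10)
    frac <- 0.3
    structured <- generate_atlas(
      geo, list(pattern_spec(c("patch", "stripe", "gradient")[i %% 3 + 1],
                             "x", frac, 2)), seed = i)
    rand <- generate_atlas(
      geo, list(pattern_spec("random", on_fraction = frac)), seed = i)
    join_count_z(structured$f[, 1], w)$z -
      join_count_z(rand$f[, 1], w)$z
  }, numeric(1))
  expect_lt(mean(deltas), 0)
  expect_gt(mean(deltas < 0), 0.9)
})

test_that("transcriptomic statistics match hand computation", {
  raw <- rbind(g1 = c(2, 2, 2, 2),
               g2 = c(0, 1, 4, 0),
               g3 = c(5, 5, 0, 5),
               g4 = c(0, 0, 0, 0),
               g5 = c(1, 3, 5, 7))
  expr <- expression_matrix(raw)
  expr$normalized <- raw   # identity transform keeps arithmetic exact
  expr$binarized <- (raw > 2) * 1
  expect_warning(st <- transcriptomic_gene_stats(expr), "CV undefined")
  expect_equal(st$sigma2[st$gene == "g1"], 0)
  expect_equal(st$cv[st$gene == "g1"], 0)
  expect_equal(st$n_zero[st$gene == "g1"], 0)
  expect_equal(st$n_zero[st$gene == "g2"], 2)
  expect_equal(st$sigma2[st$gene == "g5"], var(c(1, 3, 5, 7)))
  expect_equal(st$cv[st$gene == "g5"],
               sd(c(1, 3, 5, 7)) / mean(c(1, 3, 5, 7)))
  expect_true(is.nan(st$cv[st$gene == "g4"]))
  expect_equal(st$Hb[st$gene == "g5"], binary_entropy(0.75))
})

test_that("stat correlations recover engineered relationships", {
  spatial <- data.frame(gene = sprintf("g%02d", 1:10),
                        H = seq(0.1, 1, by = 0.1),
                        Z = -seq(1, 10))
  trans <- data.frame(gene = spatial$gene,
                      sigma2 = seq(0.1, 1, by = 0.1),   # equal to H
                      cv = rnorm(10),
                      n_zero = 10:1,
                      Hb = rnorm(10))
  ct <- correlate_stats(trans, spatial)
  expect_equal(ct["sigma2", "H"], 1)
  expect_equal(ct["n_zero", "Z"], 1)   # both decreasing sequences
  expect_error(correlate_stats(trans[1:2, ], spatial[1:2, ]), "3")
})

test_that("dropout produces the negative zeros-vs-entropy correlation", {
  geo <- generate_geometry(150, seed = 71)
  atlas <- generate_atlas(geo, default_pattern_panel(30, 5), seed = 72)
  sim <- generate_cells(atlas, geo, 150,
                        synthetic_truth(dropout_midpoint = 25, seed = 73))
  expr <- binarize_expression(normalize_expression(sim$expr), 0.1)
  st <- transcriptomic_gene_stats(expr)
  w <- knn_connectivity(geo, 10)
  sp <- atlas_spatial_stats(atlas, w)
  ct <- correlate_stats(st, sp)
  expect_lt(ct["n_zero", "H"], 0)
})

test_that("selection frequencies count team-fold panels exactly", {
  panels <- list(c("a", "b"), c("a", "c"), c("a", "b"), c("d", "b"))
  freq <- selection_frequency(panels, universe = c("a", "b", "c", "d", "e"))
  expect_equal(freq$count[freq$gene == "a"], 3)
  expect_equal(freq$count[freq$gene == "b"], 3)
  expect_equal(freq$count[freq$gene == "e"], 0)
  expect_equal(freq$gene[1:2], c("a", "b"))   # ties by name
  expect_equal(sum(freq$count), sum(lengths(panels)))
})

test_that("jaccard similarity handles the edge cases", {
  expect_equal(jaccard(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard(c("a"), c("b")), 0)
  expect_equal(jaccard(c("a", "b"), c("b", "c")), 1 / 3)
  expect_equal(jaccard(character(0), character(0)), 1)
})

test_that("the shift test matches exact enumeration on small groups", {
  x <- c(9, 10, 11, 12, 13, 14, 15, 16)
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res <- shift_test(x, y, "greater")
  expect_equal(res$p, oracle_mwu_exact(x, y, "greater"))
  expect_lt(res$p, 0.01)
  # with ties, still agrees with enumeration
  x2 <- c(3, 3, 4, 5)
  y2 <- c(1, 2, 3, 3)
  expect_equal(shift_test(x2, y2, "greater")$p,
               oracle_mwu_exact(x2, y2, "greater"))
  expect_equal(shift_test(x2, y2, "less")$p,
               oracle_mwu_exact(x2, y2, "less"))
})

test_that("the large-sample path agrees with the standard implementation", {
  withr::with_seed(44, {
    x <- rnorm(25, 0.4)
    y <- rnorm(30)
    res <- shift_test(x, y, "greater")
    ref <- wilcox.test(x, y, alternative = "greater", exact = FALSE,
                       correct = TRUE)
    expect_equal(res$U, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  })
})

test_that("fully tied groups give p = 0.5", {
  expect_equal(shift_test(rep(2, 5), rep(2, 7), "greater")$p, 0.5)
  expect_error(shift_test(numeric(0), 1:3), "non-empty")
})

test_that("the pairwise correlation census enumerates all gene pairs", {
  m <- diag(5)
  cen <- pairwise_correlation_census(m)
  expect_equal(cen$n_pairs, choose(5, 2))
  world <- small_world()
  cen2 <- pairwise_correlation_census(world$expr)
  expect_equal(cen2$n_pairs, choose(length(world$expr$genes), 2))
  expect_true(all(cen2$n_above["gt_0.5"] <= cen2$n_above["gt_0.3"]))
})
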