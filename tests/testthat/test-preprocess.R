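test_that("normalization maps zeros to zero and preserves in-cell order", {
  raw <- matrix(c(0, 5, 10, 2,
                  3, 0, 1, 7), nrow = 4,
                dimnames = list(paste0("g", 1:4), c("c1", "c2")))
  expr <- normalize_expression(expression_matrix(raw))
  expect_equal(expr$normalized["g1", "c1"], 0)   # log(1 + 0)
  # counts 5 < 10 within c1 stay ordered
  expect_lt(expr$normalized["g2", "c1"], expr$normalized["g3", "c1"])
  ranks_raw <- rank(raw[, 2])
  ranks_norm <- rank(expr$normalized[, 2])
  expect_equal(ranks_norm, ranks_raw)
})

test_that("cells with zero total UMI are reported by barcode", {
  raw <- cbind(c1 = c(1, 2), c2 = c(0, 0))
  rownames(raw) <- c("g1", "g2")
  expect_error(normalize_expression(expression_matrix(raw)), "c2")
})

test_that("binarization thresholds per gene over expressing cells", {
  # gene expressed in 4 cells with normalized values 1..4 at q = 0.5:
  # the type-7 quantile is 2.5, so cells 3 and 4 are ON
  raw <- rbind(g1 = c(1, 2, 3, 4, 0))
  expr <- expression_matrix(raw)
  expr$normalized <- rbind(g1 = c(1, 2, 3, 4, 0))
  out <- binarize_expression(expr, 0.5)
  expect_equal(unname(out$binarized["g1", ]), c(0, 0, 1, 1, 0))
})

test_that("q near zero approaches the expressed indicator", {
  # with interpolated quantiles the threshold sits just above the gene
  # minimum, so at most the minimum expressing cell per gene can differ
  # from the raw>0 indicator
  world <- small_world()
  out <- binarize_expression(world$expr, 1e-6)
  expressed <- (world$expr$raw > 0) * 1
  expect_true(all(out$binarized <= expressed))
  mismatch <- which(out$binarized != expressed, arr.ind = TRUE)
  for (k in seq_len(nrow(mismatch))) {
    g <- mismatch[k, 1]
    on <- world$expr$raw[g, ] > 0
    expect_equal(world$expr$normalized[g, mismatch[k, 2]],
                 min(world$expr$normalized[g, on]))
  }
  expect_lte(nrow(mismatch), length(world$expr$genes))
})

test_that("binarization is idempotent on a preserved binary layer", {
  world <- small_world()
  b <- world$expr$binarized
  again <- expression_matrix(raw = b, normalized = b)
  for (q in c(0.1, 0.5, 0.9)) {
    expect_equal(binarize_expression(again, q)$binarized, b)
  }
})

test_that("silent genes yield all-OFF columns with a warning", {
  raw <- rbind(g1 = c(0, 0, 0), g2 = c(1, 2, 3))
  expr <- normalize_expression(expression_matrix(raw))
  expect_warning(out <- binarize_expression(expr, 0.3), "zero cells")
  expect_equal(unname(out$binarized["g1", ]), c(0, 0, 0))
})

test_that("noiseless counts binarized near the background fraction recover the latent layer", {
  world <- small_world()
  agreement <- mean(world$expr$binarized == world$expr$latent)
  expect_gte(agreement, 0.95)
})

test_that("quantile selection recovers a known binarization quantile", {
  # cells constructed so that exactly the top 70% of each gene's
  # expressing values are truly ON (background fraction = q0 = 0.3),
  # with a value gap at the threshold
  q0 <- 0.3
  world <- small_world()
  atlas <- world$atlas
  withr::with_seed(11, {
    # one cell per bin, so the binarized-expression correlation matrix
    # can match the atlas correlation matrix exactly in the recovery
    # window
    n_cells <- nrow(atlas$f)
    true_bin <- seq_len(n_cells)
    latent <- t(atlas$f[true_bin, ])
    ng <- nrow(latent)
    norm <- matrix(0, ng, n_cells)
    raw <- matrix(0, ng, n_cells)
    for (g in seq_len(ng)) {
      on <- which(latent[g, ] == 1)
      n_bg <- round(length(on) * q0 / (1 - q0))
      bg <- sample(which(latent[g, ] == 0), min(n_bg, sum(latent[g, ] == 0)))
      norm[g, on] <- runif(length(on), 1.5, 3)
      norm[g, bg] <- runif(length(bg), 0.1, 0.9)
      raw[g, c(on, bg)] <- 1
    }
    expr <- expression_matrix(raw = raw, normalized = norm,
                              genes = atlas$genes)
    sel <- select_binarization_quantile(expr, atlas,
                                        grid = seq(0.05, 0.95, by = 0.02))
    expect_lte(abs(sel$q - q0), 0.021)
  })
})

test_that("the quantile objective matches a brute-force recomputation", {
  world <- small_world()
  genes <- world$atlas$genes[1:8]
  expr <- world$expr
  sel <- select_binarization_quantile(expr, world$atlas,
                                      shared_genes = genes,
                                      grid = c(0.2, 0.5))
  for (i in seq_len(2)) {
    q <- sel$objective$q[i]
    b <- binarize_expression(expr, q)$binarized[genes, ]
    diffs <- c()
    for (g1 in 2:length(genes)) {
      for (g2 in seq_len(g1 - 1)) {
        ce <- suppressWarnings(cor(b[g1, ], b[g2, ]))
        ca <- suppressWarnings(cor(world$atlas$f[, genes[g1]],
                                   world$atlas$f[, genes[g2]]))
        d <- ce - ca
        if (is.finite(d)) diffs <- c(diffs, d)
      }
    }
    expect_equal(sel$objective$rms[i], sqrt(mean(diffs^2)),
                 tolerance = 1e-12)
  }
})

test_that("a singleton grid returns its only quantile", {
  world <- small_world()
  sel <- select_binarization_quantile(world$expr, world$atlas,
                                      grid = 0.23)
  expect_equal(sel$q, 0.23)
  expect_error(select_binarization_quantile(world$expr, world$atlas,
                                            grid = numeric(0)),
               "non-empty")
})
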