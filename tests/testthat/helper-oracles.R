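# Independent oracles: deliberately naive, straight-from-the-formulas
# implementations used to check the package's vectorized code paths.

oracle_mcc <- function(u, v) {
  tab <- table(factor(u, c(0, 1)), factor(v, c(0, 1)))
  tp <- tab["1", "1"]; tn <- tab["0", "0"]
  fp <- tab["0", "1"]; fn <- tab["1", "0"]
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  as.numeric((tp * tn - fp * fn) / sqrt(den))
}

# Straight-from-the-formulas challenge scores for one prediction.
# All loops, no sharing with the package implementation.
oracle_scores <- function(prediction, silver, atlas, expr, geometry,
                          layer = "binarized") {
  keep <- !silver$ambiguous
  cells <- silver$cells[keep]
  eps <- silver$epsilon[keep]
  d84 <- silver$d84_ref[keep]
  p <- numeric(length(cells))
  m1 <- numeric(length(cells))
  for (j in seq_along(cells)) {
    bins <- prediction$bins[cells[j], ]
    dists <- numeric(10)
    for (i in 1:10) {
      dists[i] <- sqrt(sum((geometry$coords[bins[i], ] -
                              geometry$coords[eps[j], ])^2))
    }
    p[j] <- d84[j] / mean(dists)
    m1[j] <- oracle_mcc(atlas$f[bins[1], ], atlas$f[eps[j], ])
  }
  s1 <- sum(p / sum(p) * m1)
  s2 <- mean(p)
  panel <- prediction$gene_panel
  tmat <- expr[[layer]][panel, cells, drop = FALSE]
  m <- numeric(length(panel))
  mp <- numeric(length(panel))
  for (s in seq_along(panel)) {
    f_eps <- vapply(seq_along(cells),
                    function(j) atlas$f[eps[j], panel[s]], numeric(1))
    f_top <- vapply(seq_along(cells),
                    function(j) atlas$f[prediction$bins[cells[j], 1],
                                        panel[s]], numeric(1))
    m[s] <- oracle_mcc(tmat[s, ], f_eps)
    mp[s] <- oracle_mcc(tmat[s, ], f_top)
  }
  s3 <- sum(m / sum(m) * mp)
  list(s1 = s1, s2 = s2, s3 = s3)
}

# Monte-Carlo permutation null for the BW join count.
oracle_bw <- function(gene, w_dense) {
  0.5 * sum(w_dense * outer(gene, gene, function(a, b) (a - b)^2))
}

oracle_permutation_null <- function(gene, w_dense, n_perm, seed) {
  withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      oracle_bw(sample(gene), w_dense)
    }, numeric(1))
  })
}

# Exact one-sided Mann-Whitney p by enumerating all group assignments.
oracle_mwu_exact <- function(x, y, direction = "greater") {
  n1 <- length(x)
  r <- rank(c(x, y))
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  if (direction == "less") {
    u_obs <- n1 * length(y) - u_obs
  }
  combs <- utils::combn(n1 + length(y), n1)
  us <- apply(combs, 2, function(idx) {
    u <- u_of(idx)
    if (direction == "less") n1 * length(y) - u else u
  })
  mean(us >= u_obs)
}
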