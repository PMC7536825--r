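#' Binary entropy in bits
#'
#' `H(p) = -p log2 p - (1-p) log2(1-p)`, with `0 log 0 := 0`. Vectorized.
#'
#' @param p ON probability (or probabilities) in \[0, 1\].
#' @return Entropy in bits, in \[0, 1\].
#' @export
binary_entropy <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop_invalid("`p` must lie in [0, 1]")
  }
  term <- function(x) ifelse(x == 0, 0, -x * log2(x))
  term(p) + term(1 - p)
}

#' k-nearest-neighbor connectivity matrix
#'
#' Binary bin x bin matrix with `w[i, j] = 1` iff `j` is among the `k`
#' nearest neighbors of `i` (Euclidean distance, self excluded, distance
#' ties broken by ascending bin id). Because neighborhood membership is
#' not mutual, `w` is generally asymmetric; every row sums to `k`. The
#' sums `x1 = sum_ij w_ij`, `x2 = 1/2 sum_ij (w_ij + w_ji)^2` and
#' `x3 = sum_i (w_i. + w_.i)^2` feed the join-count null moments.
#'
#' @param geometry an [embryo_geometry].
#' @param k neighbor count (default 10).
#' @return Object of class `connectivity_matrix`: sparse `w`, `k`, and
#'   the scalar sums `x1`, `x2`, `x3`.
#' @export
knn_connectivity <- function(geometry, k = 10L) {
  stopifnot(inherits(geometry, "embryo_geometry"))
  check_scalar_number(k, "k", lower = 1, integer = TRUE)
  n <- n_bins(geometry)
  if (n <= k) stop_invalid("number of bins must exceed `k`")
  idx <- if (k == geometry$k_neighbors) {
    geometry$knn
  } else {
    knn_index(geometry$coords, as.integer(k))
  }
  w <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.vector(t(idx)),
                            x = 1, dims = c(n, n))
  ws <- w + Matrix::t(w)
  x1 <- sum(w)
  x2 <- 0.5 * sum(ws@x^2)
  x3 <- sum((Matrix::rowSums(w) + Matrix::colSums(w))^2)
  structure(list(w = w, k = as.integer(k), x1 = x1, x2 = x2, x3 = x3),
            class = "connectivity_matrix")
}

#' Join-count spatial autocorrelation statistic for a binary pattern
#'
#' Counts BW joins (ON/OFF neighbor pairs), `BW = 1/2 sum_ij w_ij
#' (G_i - G_j)^2`, and compares them to the randomization null that
#' permutes the `n_B` ON labels over bins: `E[BW] = x1 n_B n_W / n_(2)`
#' and a closed-form variance built from `x1, x2, x3` and falling
#' factorials `n_(r) = n(n-1)...(n-r+1)` (validated against an exhaustive
#' permutation oracle). `Z = (BW - E[BW]) / sqrt(var)`; negative `Z`
#' means fewer boundaries than expected, i.e. positive spatial
#' autocorrelation (clustering); positive `Z` means dispersion. A
#' constant pattern has no boundaries and `Z` is NaN (with a warning).
#'
#' @param gene binary vector over bins.
#' @param w a [knn_connectivity()] result.
#' @return List with `bw_obs`, `e_bw`, `var_bw`, `z`.
#' @export
join_count_z <- function(gene, w) {
  stopifnot(inherits(w, "connectivity_matrix"))
  n <- nrow(w$w)
  if (length(gene) != n) {
    stop_invalid("`gene` length must equal the number of bins")
  }
  check_binary(gene, "gene")
  g <- as.numeric(gene)
  # 1/2 sum_ij w_ij (g_i - g_j)^2, via the sparse triplet form
  tw <- methods::as(w$w, "TsparseMatrix")
  bw_obs <- 0.5 * sum((g[tw@i + 1L] - g[tw@j + 1L])^2)
  n_b <- sum(g == 1)
  n_w <- n - n_b
  if (n_b == 0L || n_w == 0L) {
    warning("constant pattern: join-count Z undefined", call. = FALSE)
    return(list(bw_obs = bw_obs, e_bw = 0, var_bw = 0, z = NaN))
  }
  nn2 <- n * (n - 1)
  nn3 <- nn2 * (n - 2)
  nn4 <- nn3 * (n - 3)
  e_bw <- 0.5 * w$x1 * 2 * n_b * n_w / nn2
  e_bw2 <- 0.25 * (2 * w$x2 * n_b * n_w / nn2 +
                   (w$x3 - 2 * w$x2) * n_b * n_w * (n_b + n_w - 2) / nn3 +
                   4 * (w$x1^2 + w$x2 - w$x3) *
                     n_b * (n_b - 1) * n_w * (n_w - 1) / nn4)
  var_bw <- e_bw2 - e_bw^2
  list(bw_obs = bw_obs, e_bw = e_bw, var_bw = var_bw,
       z = (bw_obs - e_bw) / sqrt(var_bw))
}

#' Spatial statistics of every atlas gene
#'
#' Per-gene ON fraction `p`, binary entropy `H` (bits), and the
#' join-count quantities from [join_count_z()].
#'
#' @param atlas an [insitu_atlas].
#' @param w a [knn_connectivity()] result for the matching geometry.
#' @return Data frame with one row per gene: `gene`, `p`, `H`, `bw_obs`,
#'   `e_bw`, `var_bw`, `Z`.
#' @export
atlas_spatial_stats <- function(atlas, w) {
  stopifnot(inherits(atlas, "insitu_atlas"))
  rows <- lapply(seq_along(atlas$genes), function(j) {
    g <- atlas$f[, j]
    jc <- suppressWarnings(join_count_z(g, w))
    data.frame(gene = atlas$genes[j], p = mean(g),
               H = binary_entropy(mean(g)),
               bw_obs = jc$bw_obs, e_bw = jc$e_bw, var_bw = jc$var_bw,
               Z = jc$z, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Transcriptomic statistics of every gene
#'
#' Per gene: variance `sigma2` and coefficient of variation `cv` of the
#' normalized expression across cells, the number of cells with zero raw
#' count `n_zero`, and the binary entropy `Hb` of the binarized calls'
#' ON fraction across cells. Zeros are counted on the raw layer because
#' they are only meaningful before transformation; `cv` is NaN (with a
#' warning) for genes with zero mean normalized expression.
#'
#' @param expr an [expression_matrix] with raw and binarized layers
#'   (normalized required for `sigma2`/`cv`).
#' @return Data frame with columns `gene`, `sigma2`, `cv`, `n_zero`, `Hb`.
#' @export
transcriptomic_gene_stats <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  norm <- get_layer(expr, "normalized")
  bin <- get_layer(expr, "binarized")
  mu <- rowMeans(norm)
  sigma2 <- apply(norm, 1, stats::var)
  cv <- ifelse(mu == 0, NaN, sqrt(sigma2) / mu)
  if (any(mu == 0)) {
    warning("gene(s) with zero mean expression: CV undefined",
            call. = FALSE)
  }
  data.frame(gene = expr$genes, sigma2 = sigma2, cv = cv,
             n_zero = rowSums(expr$raw == 0),
             Hb = binary_entropy(rowMeans(bin)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Correlate transcriptomic and spatial gene properties
#'
#' Correlation, across the shared genes, of each transcriptomic statistic
#' (`sigma2`, `cv`, `n_zero`, `Hb`) with each spatial property (`H`,
#' `Z`). Genes with undefined entries are dropped pairwise; fewer than 3
#' usable genes for a pair is an error.
#'
#' @param trans output of [transcriptomic_gene_stats()].
#' @param spatial output of [atlas_spatial_stats()].
#' @param shared_genes genes to use (default: intersection).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return 4 x 2 numeric matrix of correlations.
#' @export
correlate_stats <- function(trans, spatial,
                            shared_genes = intersect(trans$gene,
                                                     spatial$gene),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(shared_genes) < 3L) stop_invalid("need at least 3 shared genes")
  ti <- match(shared_genes, trans$gene)
  si <- match(shared_genes, spatial$gene)
  tstats <- c("sigma2", "cv", "n_zero", "Hb")
  sstats <- c("H", "Z")
  out <- matrix(NA_real_, length(tstats), length(sstats),
                dimnames = list(tstats, sstats))
  for (a in tstats) {
    for (b in sstats) {
      x <- trans[[a]][ti]
      y <- spatial[[b]][si]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3L) {
        stop_invalid(sprintf("fewer than 3 usable genes for %s vs %s", a, b))
      }
      out[a, b] <- stats::cor(x[ok], y[ok], method = method)
    }
  }
  out
}

#' Count how often each gene was selected
#'
#' Counts, over all (team, fold) panels, how many contain each gene.
#' Output is ordered by count descending, ties by gene name.
#'
#' @param panels list of character vectors (one per team-fold panel).
#' @param universe optional gene universe; genes never selected are then
#'   reported with count 0.
#' @return Data frame with columns `gene`, `count`.
#' @export
selection_frequency <- function(panels, universe = NULL) {
  if (length(panels) == 0L) stop_invalid("`panels` must be non-empty")
  all_genes <- unlist(panels, use.names = FALSE)
  universe <- sort(unique(c(universe, all_genes)))
  counts <- vapply(universe, function(g) {
    sum(vapply(panels, function(p) g %in% p, logical(1)))
  }, integer(1))
  ord <- order(-counts, universe)
  data.frame(gene = universe[ord], count = counts[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Jaccard similarity of two sets
#'
#' `|A intersect B| / |A union B|`; two empty sets give 1 by convention.
#'
#' @param a,b vectors treated as sets.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' One-sided Mann-Whitney U shift test
#'
#' Rank-sum test of location shift between the selected and unselected
#' groups. Uses exact enumeration over all group assignments when both
#' groups have at most 8 values (ties handled by enumerating mid-rank
#' statistics), otherwise the tie-corrected normal approximation with
#' continuity correction. When the tie-corrected variance is zero (all
#' values identical), p = 0.5.
#'
#' @param selected_values,unselected_values numeric vectors (non-empty).
#' @param direction `"greater"` tests whether selected values are shifted
#'   upward relative to unselected, `"less"` the reverse.
#' @return List with `U` (statistic of the selected group) and `p`.
#' @export
shift_test <- function(selected_values, unselected_values,
                       direction = c("greater", "less")) {
  direction <- match.arg(direction)
  x <- as.numeric(selected_values)
  y <- as.numeric(unselected_values)
  if (length(x) == 0L || length(y) == 0L) {
    stop_invalid("both groups must be non-empty")
  }
  n1 <- length(x); n2 <- length(y)
  u_stat <- function(ranks_x) sum(ranks_x) - n1 * (n1 + 1) / 2
  r <- rank(c(x, y))
  if (all(c(x, y) == x[1])) {
    # full tie: no evidence of shift in either direction
    return(list(U = u_stat(r[seq_len(n1)]), p = 0.5))
  }
  u <- u_stat(r[seq_len(n1)])
  u_dir <- if (direction == "greater") u else n1 * n2 - u
  if (n1 <= 8L && n2 <= 8L) {
    # exact: enumerate which positions of the pooled (tied) ranks belong
    # to the selected group
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) {
      ui <- u_stat(r[idx])
      if (direction == "greater") ui else n1 * n2 - ui
    })
    p <- mean(us >= u_dir)
  } else {
    mu <- n1 * n2 / 2
    nties <- table(r)
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * (n + 1 - sum(nties^3 - nties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 0.5
    } else {
      z <- (u_dir - mu - 0.5) / sqrt(sigma2)
      p <- stats::pnorm(z, lower.tail = FALSE)
    }
  }
  list(U = u, p = p)
}

#' Census of pairwise gene-gene correlations
#'
#' Enumerates all unordered gene pairs of a correlation matrix's strict
#' lower triangle and counts how many exceed the given absolute
#' thresholds — the book-keeping behind statements like "59 of all
#' possible 3,486 pairs have |r| > 0.5".
#'
#' @param x either a square correlation matrix or an
#'   [expression_matrix] (then the Pearson correlation of the normalized
#'   layer across cells is used).
#' @param genes genes to restrict to (expression input only).
#' @param thresholds absolute-correlation thresholds to count.
#' @return List with `n_genes`, `n_pairs`, `correlations` (lower-triangle
#'   vector) and `n_above` (named count per threshold).
#' @export
pairwise_correlation_census <- function(x, genes = NULL,
                                        thresholds = c(0.3, 0.5)) {
  if (inherits(x, "expression_matrix")) {
    m <- get_layer(x, "normalized")
    if (!is.null(genes)) m <- m[genes, , drop = FALSE]
    cm <- suppressWarnings(stats::cor(t(m)))
  } else {
    cm <- as.matrix(x)
    if (nrow(cm) != ncol(cm)) stop_invalid("correlation matrix must be square")
  }
  vals <- cm[lower.tri(cm)]
  list(n_genes = nrow(cm),
       n_pairs = length(vals),
       correlations = vals,
       n_above = stats::setNames(
         vapply(thresholds, function(th) sum(abs(vals) > th, na.rm = TRUE),
                integer(1)),
         paste0("gt_", thresholds)))
}
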