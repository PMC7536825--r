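#' Per-cell distance weights of a prediction
#'
#' For each scored cell, `d_K` is the mean Euclidean distance of the 10
#' predicted bins to the ground-truth position, and `p_K = d84_ref / d_K`
#' is the inverse-distance weight relative to the silver-standard
#' reference list. `p_K = 1` when the prediction equals the reference
#' list; tighter lists give `p_K > 1`.
#'
#' @param prediction a [location_prediction].
#' @param silver a [build_silver_standard()] result.
#' @param geometry the [embryo_geometry].
#' @param cells cells to evaluate; defaults to all silver cells. Every
#'   requested cell must be present in the prediction (missing cells are
#'   an error, not a silent exclusion).
#' @return Data frame with columns `cell`, `d_K`, `p_K`.
#' @export
location_weights <- function(prediction, silver, geometry,
                             cells = silver$cells) {
  stopifnot(inherits(prediction, "location_prediction"),
            inherits(silver, "silver_standard"))
  missing <- setdiff(cells, prediction$cells)
  if (length(missing)) {
    stop_invalid("prediction is missing silver-standard cell(s): ",
                 paste(utils::head(missing, 5), collapse = ", "))
  }
  si <- match(cells, silver$cells)
  if (anyNA(si)) stop_invalid("cell(s) absent from the silver standard")
  d_k <- vapply(seq_along(cells), function(j) {
    eps <- silver$epsilon[si[j]]
    mean(bin_distances(geometry, prediction$bins[cells[j], ],
                       geometry$coords[eps, ]))
  }, numeric(1))
  if (any(d_k == 0)) {
    stop_invalid("d_K = 0 encountered (co-located predicted bins)")
  }
  data.frame(cell = cells, d_K = d_k, p_K = silver$d84_ref[si] / d_k,
             stringsAsFactors = FALSE)
}

scored_cells <- function(silver) silver$cells[!silver$ambiguous]

#' Challenge score s1: distance-weighted atlas-profile agreement
#'
#' Weighted average, over non-ambiguous cells, of the MCC between the
#' full-panel atlas profile of the ground-truth bin and that of the
#' predicted most probable bin, with weights `p_K(c) / sum(p_K)`.
#'
#' @inheritParams location_weights
#' @param atlas the reference [insitu_atlas] (full panel profiles).
#' @return A number in \[-1, 1\].
#' @export
score_s1 <- function(prediction, silver, atlas, geometry) {
  cells <- scored_cells(silver)
  if (length(cells) == 0L) stop_invalid("no non-ambiguous cells to score")
  w <- location_weights(prediction, silver, geometry, cells)$p_K
  si <- match(cells, silver$cells)
  m1 <- vapply(seq_along(cells), function(j) {
    mcc(atlas$f[prediction$bins[cells[j], 1], ],
        atlas$f[silver$epsilon[si[j]], ])
  }, numeric(1))
  sum(w * m1) / sum(w)
}

#' Challenge score s2: mean inverse-distance accuracy
#'
#' The average of the inverse-distance weights `p_K` over non-ambiguous
#' cells. Equals 1 for the reference lists themselves and exceeds 1 when
#' predicted lists are tighter around the ground truth.
#'
#' @inheritParams location_weights
#' @return A non-negative number.
#' @export
score_s2 <- function(prediction, silver, geometry) {
  cells <- scored_cells(silver)
  if (length(cells) == 0L) stop_invalid("no non-ambiguous cells to score")
  mean(location_weights(prediction, silver, geometry, cells)$p_K)
}

#' Challenge score s3: gene-wise spatial pattern reconstruction
#'
#' For each panel gene `s`, `m_s` is the MCC across cells between the
#' binarized expression of `s` and the atlas value of `s` at the
#' ground-truth bins, and `m'_s` the same MCC at the predicted top-1
#' bins; `s3 = sum_s (m_s / sum_i m_i) * m'_s`.
#'
#' @inheritParams score_s1
#' @param expr an [expression_matrix] with binarized calls.
#' @param gene_panel panel genes; default the prediction's panel.
#' @param layer expression layer holding the ON/OFF calls.
#' @return The s3 score.
#' @export
score_s3 <- function(prediction, silver, atlas, expr,
                     gene_panel = prediction$gene_panel,
                     layer = "binarized") {
  if (is.null(gene_panel)) stop_invalid("no gene panel available for s3")
  cells <- scored_cells(silver)
  if (length(cells) == 0L) stop_invalid("no non-ambiguous cells to score")
  si <- match(cells, silver$cells)
  t_bin <- get_layer(expr, layer)[gene_panel, cells, drop = FALSE]
  f_eps <- t(atlas$f[silver$epsilon[si], gene_panel, drop = FALSE])
  f_top <- t(atlas$f[prediction$bins[cells, 1], gene_panel, drop = FALSE])
  m <- vapply(seq_along(gene_panel), function(s) {
    mcc(t_bin[s, ], f_eps[s, ])
  }, numeric(1))
  mp <- vapply(seq_along(gene_panel), function(s) {
    mcc(t_bin[s, ], f_top[s, ])
  }, numeric(1))
  if (sum(m) == 0) stop_invalid("degenerate panel: sum of reference MCCs is 0")
  sum(m / sum(m) * mp)
}

#' Score a submission with all three challenge metrics
#'
#' Drops ambiguous cells, then computes s1, s2 and s3.
#'
#' @inheritParams score_s3
#' @return Object of class `score_triple`: list with `s1`, `s2`, `s3`,
#'   `n_cells_scored`.
#' @export
score_submission <- function(prediction, silver, atlas, expr, geometry,
                             gene_panel = prediction$gene_panel,
                             layer = "binarized") {
  out <- list(
    s1 = score_s1(prediction, silver, atlas, geometry),
    s2 = score_s2(prediction, silver, geometry),
    s3 = score_s3(prediction, silver, atlas, expr, gene_panel, layer),
    n_cells_scored = sum(!silver$ambiguous)
  )
  structure(out, class = "score_triple")
}

#' @export
print.score_triple <- function(x, ...) {
  cat(sprintf("s1 = %.4f  s2 = %.4f  s3 = %.4f  (N = %d cells)\n",
              x$s1, x$s2, x$s3, x$n_cells_scored))
  invisible(x)
}

# Precompute, for one team, everything the bootstrap needs per scored cell:
# p_K, top-1 atlas-profile MCC, and the per-gene binary triples for s3.
precompute_team <- function(prediction, silver, atlas, expr, geometry,
                            cells, gene_panel, layer) {
  si <- match(cells, silver$cells)
  w <- location_weights(prediction, silver, geometry, cells)$p_K
  m1 <- vapply(seq_along(cells), function(j) {
    mcc(atlas$f[prediction$bins[cells[j], 1], ],
        atlas$f[silver$epsilon[si[j]], ])
  }, numeric(1))
  f_top <- t(atlas$f[prediction$bins[cells, 1], gene_panel, drop = FALSE])
  list(p = w, m1 = m1, f_top = f_top)
}

# MCC per row between two K x N binary matrices, over columns `idx`.
rowwise_mcc <- function(a, b) {
  tp <- rowSums(a * b)
  fp <- rowSums((1 - a) * b)
  fn <- rowSums(a * (1 - b))
  tn <- ncol(a) - tp - fp - fn
  num <- tp * tn - fp * fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- numeric(length(tp))
  pos <- den > 0
  out[pos] <- num[pos] / sqrt(den[pos])
  out
}

#' Bootstrap ranking of team submissions
#'
#' For each bootstrap replicate, the scored (non-ambiguous) cells are
#' resampled with replacement — the same resampled index set for every
#' team, making the comparison paired — the three scores are recomputed,
#' teams are ranked per score (average ranks on ties, lower rank =
#' better), and the three ranks are averaged into the replicate's final
#' rank. Reference distances are fixed at their silver-standard values
#' across replicates.
#'
#' @param submissions named list of [location_prediction] objects (>= 2).
#' @inheritParams score_s3
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return Object of class `ranking_result`: `ranks` (teams x replicates
#'   matrix), `mean_rank`, `bayes_factors` (teams x teams matrix of
#'   `bayes_factor(Ti, Tj)`).
#' @export
bootstrap_rank <- function(submissions, silver, atlas, expr, geometry,
                           n_boot = 1000L, seed = 1L, layer = "binarized") {
  if (length(submissions) < 2L) stop_invalid("need at least two teams")
  check_scalar_number(n_boot, "n_boot", lower = 1, integer = TRUE)
  teams <- names(submissions) %||% paste0("team", seq_along(submissions))
  cells <- scored_cells(silver)
  n <- length(cells)
  si <- match(cells, silver$cells)
  pre <- lapply(submissions, function(p) {
    precompute_team(p, silver, atlas, expr, geometry, cells,
                    p$gene_panel, layer)
  })
  panels <- lapply(submissions, `[[`, "gene_panel")
  t_bins <- lapply(panels, function(gp) {
    get_layer(expr, layer)[gp, cells, drop = FALSE]
  })
  f_eps <- lapply(panels, function(gp) {
    t(atlas$f[silver$epsilon[si], gp, drop = FALSE])
  })
  ranks <- matrix(NA_real_, length(submissions), n_boot,
                  dimnames = list(teams, NULL))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      s_mat <- vapply(seq_along(submissions), function(ti) {
        p <- pre[[ti]]$p[idx]
        s1 <- sum(p * pre[[ti]]$m1[idx]) / sum(p)
        s2 <- mean(p)
        tb <- t_bins[[ti]][, idx, drop = FALSE]
        m <- rowwise_mcc(tb, f_eps[[ti]][, idx, drop = FALSE])
        mp <- rowwise_mcc(tb, pre[[ti]]$f_top[, idx, drop = FALSE])
        s3 <- if (sum(m) == 0) NA_real_ else sum(m / sum(m) * mp)
        c(s1, s2, s3)
      }, numeric(3))
      r <- apply(s_mat, 1, function(s) rank(-s, ties.method = "average"))
      ranks[, b] <- rowMeans(r)
    }
  })
  bf <- matrix(NA_real_, length(teams), length(teams),
               dimnames = list(teams, teams))
  for (i in seq_along(teams)) {
    for (j in seq_along(teams)) {
      if (i != j) bf[i, j] <- bayes_factor(ranks[i, ], ranks[j, ])
    }
  }
  structure(list(ranks = ranks, mean_rank = rowMeans(ranks),
                 bayes_factors = bf, n_boot = n_boot),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("ranking_result: %d teams, %d bootstrap replicates\n",
              nrow(x$ranks), x$n_boot))
  print(round(sort(x$mean_rank), 3))
  invisible(x)
}

#' Bayes factor of two teams' bootstrap ranks
#'
#' The ratio of replicates in which team 1 outranks team 2 (strictly
#' lower rank) to replicates in which it is outranked. Ties count for
#' neither side. All wins gives `Inf`; all ties gives 1. A value of 3 or
#' more is conventionally read as significantly better performance.
#'
#' @param ranks_t1,ranks_t2 equal-length vectors of per-replicate ranks.
#' @return A non-negative number, possibly `Inf`.
#' @export
bayes_factor <- function(ranks_t1, ranks_t2) {
  if (length(ranks_t1) != length(ranks_t2)) {
    stop_invalid("rank vectors differ in length")
  }
  if (length(ranks_t1) == 0L) stop_invalid("need at least one replicate")
  wins <- sum(ranks_t1 < ranks_t2)
  losses <- sum(ranks_t1 > ranks_t2)
  if (losses == 0L) {
    if (wins == 0L) return(1)
    return(Inf)
  }
  wins / losses
}
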