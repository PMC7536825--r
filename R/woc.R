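#' Configuration of the wisdom-of-crowds location consensus
#'
#' @param k_max maximum cluster count tried by the elbow scan (default
#'   15).
#' @param n_restarts k-means restarts per k (default 10; best
#'   within-cluster sum of squares kept).
#' @param elbow_gain_threshold fraction of the total point scatter below
#'   which an additional cluster's between-cluster sum-of-squares gain
#'   counts as saturated (default 0.10).
#' @param seed integer seed making the consensus deterministic despite
#'   k-means restarts.
#' @return A `consensus_config` list.
#' @export
consensus_config <- function(k_max = 15L, n_restarts = 10L,
                             elbow_gain_threshold = 0.10, seed = 1L) {
  check_scalar_number(k_max, "k_max", lower = 1, integer = TRUE)
  check_scalar_number(n_restarts, "n_restarts", lower = 1, integer = TRUE)
  check_scalar_number(elbow_gain_threshold, "elbow_gain_threshold")
  if (elbow_gain_threshold <= 0 || elbow_gain_threshold >= 1) {
    stop_invalid("`elbow_gain_threshold` must lie strictly inside (0, 1)")
  }
  structure(list(k_max = as.integer(k_max),
                 n_restarts = as.integer(n_restarts),
                 elbow_gain_threshold = elbow_gain_threshold,
                 seed = as.integer(seed)),
            class = "consensus_config")
}

# Elbow scan: smallest k whose successor's between-SS gain saturates.
elbow_k <- function(coords, k_max, n_restarts, threshold) {
  n_distinct <- nrow(unique(coords))
  k_max <- min(k_max, n_distinct - 1L)
  if (k_max <= 1L) return(list(k = 1L, fit = NULL))
  total_ss <- sum(scale(coords, scale = FALSE)^2)
  fits <- vector("list", k_max)
  between <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- suppressWarnings(
      stats::kmeans(coords, centers = k, nstart = n_restarts,
                    iter.max = 50)
    )
    between[k] <- fits[[k]]$betweenss
  }
  k_sel <- k_max
  for (k in 2:k_max) {
    gain <- (between[k] - between[k - 1]) / total_ss
    if (gain < threshold) {
      k_sel <- k - 1L
      break
    }
  }
  list(k = k_sel, fit = fits[[k_sel]])
}

#' Wisdom-of-crowds consensus of one cell's predicted locations
#'
#' Pools the distinct bins predicted by the teams for one cell (a bin's
#' frequency = number of teams listing it), clusters the pooled bins' 3-D
#' coordinates by k-means with the elbow rule, picks the cluster with the
#' highest mean member frequency, and ranks its members by frequency
#' (ties: distance to the cluster centroid, then bin id). If the winning
#' cluster holds fewer than 10 bins, the remaining pooled bins are
#' appended under the same ordering rule relative to the winning
#' centroid. Always returns exactly 10 distinct bins.
#'
#' @param per_team_lists list (or matrix with teams as rows) of ordered
#'   10-bin predictions for a single cell.
#' @param geometry the [embryo_geometry].
#' @param config a [consensus_config()].
#' @return Integer vector of 10 bin ids, consensus-best first.
#' @export
woc_locations <- function(per_team_lists, geometry,
                          config = consensus_config()) {
  stopifnot(inherits(geometry, "embryo_geometry"),
            inherits(config, "consensus_config"))
  if (is.matrix(per_team_lists)) {
    per_team_lists <- split(per_team_lists, row(per_team_lists))
  }
  if (length(per_team_lists) == 0L) stop_invalid("no team predictions given")
  lists <- lapply(per_team_lists, function(x) {
    x <- as.integer(x)
    if (length(x) != 10L || anyDuplicated(x) ||
        any(x < 1L | x > n_bins(geometry))) {
      stop_invalid("each team list must be 10 distinct valid bin ids")
    }
    x
  })
  pool <- sort(unique(unlist(lists)))
  freq <- vapply(pool, function(b) {
    sum(vapply(lists, function(l) b %in% l, logical(1)))
  }, integer(1))
  coords <- geometry$coords[pool, , drop = FALSE]
  res <- with_seed(config$seed, {
    elb <- elbow_k(coords, config$k_max, config$n_restarts,
                   config$elbow_gain_threshold)
    if (is.null(elb$fit)) {
      cluster <- rep(1L, length(pool))
      centers <- matrix(colMeans(coords), 1)
    } else {
      cluster <- elb$fit$cluster
      centers <- elb$fit$centers
    }
    list(cluster = cluster, centers = centers)
  })
  mean_freq <- tapply(freq, res$cluster, mean)
  sizes <- tapply(freq, res$cluster, length)
  min_bin <- tapply(pool, res$cluster, min)
  cl_ids <- as.integer(names(mean_freq))
  # winner: highest mean frequency; deterministic tie-breaks by larger
  # size, then smallest member bin id
  win <- cl_ids[order(-mean_freq, -sizes, min_bin)][1]
  centroid <- res$centers[win, ]
  dist_c <- bin_distances(geometry, pool, centroid)
  in_win <- res$cluster == win
  ord_win <- order(-freq[in_win], dist_c[in_win], pool[in_win])
  ranked <- pool[in_win][ord_win]
  if (length(ranked) < 10L) {
    rest <- !in_win
    ord_rest <- order(-freq[rest], dist_c[rest], pool[rest])
    ranked <- c(ranked, pool[rest][ord_rest])
  }
  if (length(ranked) < 10L) {
    stop_invalid("fewer than 10 distinct bins in the pooled predictions")
  }
  ranked[seq_len(10L)]
}

#' Wisdom-of-crowds consensus over whole submissions
#'
#' Applies [woc_locations()] cell by cell to a list of team submissions
#' covering the same cells.
#'
#' @param submissions list of [location_prediction] objects.
#' @param geometry the [embryo_geometry].
#' @param config a [consensus_config()].
#' @param gene_panel panel recorded on the consensus prediction (e.g. the
#'   most frequently selected genes); default the first team's panel.
#' @return A [location_prediction] holding the consensus.
#' @export
woc_predictions <- function(submissions, geometry,
                            config = consensus_config(),
                            gene_panel = NULL) {
  if (length(submissions) == 0L) stop_invalid("no submissions given")
  cells <- submissions[[1]]$cells
  for (s in submissions) {
    if (!identical(sort(s$cells), sort(cells))) {
      stop_invalid("submissions cover different cell sets")
    }
  }
  seeds <- derive_seeds(config$seed, length(cells))
  bins <- t(vapply(seq_along(cells), function(ci) {
    cfg <- config
    cfg$seed <- seeds[ci]
    woc_locations(lapply(submissions, function(s) s$bins[cells[ci], ]),
                  geometry, cfg)
  }, integer(10)))
  location_prediction(bins, cells = cells,
                      gene_panel = gene_panel %||%
                        submissions[[1]]$gene_panel)
}

#' Wisdom-of-crowds gene panel
#'
#' The `K` most frequently selected genes; ties at the boundary are
#' broken alphabetically.
#'
#' @param frequency_table output of [selection_frequency()].
#' @param K panel size.
#' @return Character vector of `K` gene names.
#' @export
woc_gene_panel <- function(frequency_table, K) {
  check_scalar_number(K, "K", lower = 0, integer = TRUE)
  if (K > nrow(frequency_table)) {
    stop_invalid("`K` exceeds the size of the gene universe")
  }
  if (K == 0L) {
    warning("empty panel requested", call. = FALSE)
    return(character(0))
  }
  # frequency_table is already ordered (count desc, gene asc)
  ord <- order(-frequency_table$count, frequency_table$gene)
  frequency_table$gene[ord][seq_len(K)]
}

#' Validate a gene panel against a random-panel null
#'
#' Maps and scores the panel, then `n_null` uniformly random equal-size
#' panels drawn without replacement from the atlas gene universe, and
#' reports the panel's percentile per metric under the empirical
#' distribution of the null scores (fraction of null values <= panel
#' value, times 100).
#'
#' @param panel character vector of panel genes.
#' @param atlas,expr,silver,geometry the reference data; cells are scored
#'   against `silver` exactly as in the challenge.
#' @param n_null number of random panels (default 100).
#' @param seed integer seed.
#' @param layer expression layer holding the ON/OFF calls.
#' @return List with `panel_scores` (a `score_triple`), `null_scores`
#'   (n_null x 3 matrix), and `percentile` (named vector, s1/s2/s3).
#' @export
validate_panel_against_null <- function(panel, atlas, expr, silver,
                                        geometry, n_null = 100L,
                                        seed = 1L, layer = "binarized") {
  check_scalar_number(n_null, "n_null", lower = 1, integer = TRUE)
  if (!all(panel %in% atlas$genes)) {
    stop_invalid("panel gene(s) not in the atlas universe")
  }
  score_panel <- function(genes) {
    pred <- map_cells(expr, atlas, gene_panel = genes, layer = layer)
    s <- score_submission(pred, silver, atlas, expr, geometry,
                          layer = layer)
    c(s1 = s$s1, s2 = s$s2, s3 = s$s3)
  }
  panel_scores <- score_panel(panel)
  null_panels <- with_seed(seed, {
    lapply(seq_len(n_null), function(i) sample(atlas$genes, length(panel)))
  })
  null_scores <- t(vapply(null_panels, score_panel, numeric(3)))
  percentile <- vapply(c("s1", "s2", "s3"), function(m) {
    100 * mean(null_scores[, m] <= panel_scores[m])
  }, numeric(1))
  list(panel_scores = structure(as.list(c(panel_scores,
                                          n_cells_scored =
                                            sum(!silver$ambiguous))),
                                class = "score_triple"),
       null_scores = null_scores,
       percentile = percentile)
}
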