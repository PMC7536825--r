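#' Parameters of the synthetic dissociated-cell generator
#'
#' @param flip_prob probability in \[0, 1\] of flipping each gene's latent
#'   ON/OFF state per cell, emulating biological and technical deviation
#'   of a cell's profile from its bin's atlas row.
#' @param depth_mean mean total UMI per cell (> 0).
#' @param dropout_midpoint gene mean-count scale at which the dropout
#'   probability is 0.5; `0` disables dropout.
#' @param dropout_slope slope of the logistic dropout curve in log
#'   mean-scale (default 1.5).
#' @param nb_dispersion negative-binomial dispersion of ON counts
#'   (default 0.2, i.e. `size = 5`).
#' @param off_background mean of the Poisson background counts of OFF
#'   genes (default 0.05).
#' @param seed integer seed.
#' @return A `synthetic_truth` parameter object (the per-cell true bins
#'   are filled in by [generate_cells()]).
#' @export
synthetic_truth <- function(flip_prob = 0, depth_mean = 5000,
                            dropout_midpoint = 0, dropout_slope = 1.5,
                            nb_dispersion = 0.2, off_background = 0.05,
                            seed = 1L) {
  check_scalar_number(flip_prob, "flip_prob", lower = 0, upper = 1)
  check_scalar_number(depth_mean, "depth_mean")
  if (depth_mean <= 0) stop_invalid("`depth_mean` must be positive")
  check_scalar_number(dropout_midpoint, "dropout_midpoint", lower = 0)
  check_scalar_number(dropout_slope, "dropout_slope", lower = 0)
  check_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  check_scalar_number(off_background, "off_background", lower = 0)
  structure(list(true_bin_per_cell = NULL, flip_prob = flip_prob,
                 depth_mean = depth_mean,
                 dropout_midpoint = dropout_midpoint,
                 dropout_slope = dropout_slope,
                 nb_dispersion = nb_dispersion,
                 off_background = off_background,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Generate synthetic dissociated cells with known true bins
#'
#' Each cell is assigned a true bin uniformly at random; its latent
#' ON/OFF profile is the atlas row of that bin with independent
#' Bernoulli(`flip_prob`) flips. ON genes receive overdispersed
#' negative-binomial counts with gene-specific lognormal mean scales
#' (cell totals average `depth_mean`); OFF genes receive sparse Poisson
#' background counts. Dropout forces a count to zero with probability
#' decreasing in the gene's mean scale along a logistic curve centered
#' at `dropout_midpoint`, reproducing the excess of zeros among lowly
#' expressed genes seen in droplet scRNA-seq. The latent profile is
#' retained as the `latent` layer.
#'
#' @param atlas an [insitu_atlas].
#' @param geometry the matching [embryo_geometry].
#' @param n_cells number of cells (>= 1).
#' @param truth a [synthetic_truth()] parameter object.
#' @return List with `expr` (an [expression_matrix] with `raw` and
#'   `latent` layers) and `truth` (the input parameters with
#'   `true_bin_per_cell` filled in).
#' @export
generate_cells <- function(atlas, geometry, n_cells, truth = synthetic_truth()) {
  stopifnot(inherits(atlas, "insitu_atlas"),
            inherits(geometry, "embryo_geometry"),
            inherits(truth, "synthetic_truth"))
  check_scalar_number(n_cells, "n_cells", lower = 1, integer = TRUE)
  if (nrow(atlas$f) != n_bins(geometry)) {
    stop_invalid("atlas and geometry disagree on the number of bins")
  }
  n_genes <- ncol(atlas$f)
  cells <- sprintf("cell%04d", seq_len(n_cells))
  out <- with_seed(truth$seed, {
    true_bin <- sample.int(n_bins(geometry), n_cells, replace = TRUE)
    latent <- t(atlas$f[true_bin, , drop = FALSE])   # genes x cells
    if (truth$flip_prob > 0) {
      flips <- matrix(stats::runif(n_genes * n_cells) < truth$flip_prob,
                      n_genes, n_cells)
      latent[flips] <- 1 - latent[flips]
    }
    # gene-specific expression scales (lognormal), fixed per dataset
    scales <- stats::rlnorm(n_genes, meanlog = log(20), sdlog = 0.6)
    raw <- matrix(0, n_genes, n_cells)
    size <- if (truth$nb_dispersion > 0) 1 / truth$nb_dispersion else Inf
    for (c_i in seq_len(n_cells)) {
      on <- latent[, c_i] == 1
      if (any(on)) {
        mu <- truth$depth_mean * scales[on] / sum(scales[on])
        raw[on, c_i] <- if (is.finite(size)) {
          stats::rnbinom(sum(on), mu = mu, size = size)
        } else {
          stats::rpois(sum(on), mu)
        }
      }
      if (any(!on) && truth$off_background > 0) {
        raw[!on, c_i] <- stats::rpois(sum(!on), truth$off_background)
      }
    }
    if (truth$dropout_midpoint > 0) {
      # dropout probability falls with the gene's mean-count scale
      p_drop <- stats::plogis(-truth$dropout_slope *
                                (log(scales) - log(truth$dropout_midpoint)))
      drop <- matrix(stats::runif(n_genes * n_cells), n_genes, n_cells) <
        p_drop
      raw[drop] <- 0
    }
    list(true_bin = true_bin, latent = latent, raw = raw)
  })
  truth$true_bin_per_cell <- stats::setNames(out$true_bin, cells)
  expr <- expression_matrix(out$raw, genes = atlas$genes, cells = cells,
                            latent = out$latent)
  list(expr = expr, truth = truth)
}

#' Generate a synthetic ensemble of team predictions
#'
#' Each synthetic team's 10-list per cell starts from the silver-standard
#' reference list; every entry is independently replaced with probability
#' `corruption` by a bin drawn from the neighborhood (self plus k nearest
#' neighbors) of a random wrong bin. `corruption = 0` reproduces the
#' silver lists exactly.
#'
#' @param silver a [build_silver_standard()] result.
#' @param geometry the [embryo_geometry].
#' @param n_teams number of teams (>= 1).
#' @param corruption per-entry replacement probability in \[0, 1\].
#' @param seed integer seed.
#' @param gene_panel panel recorded on each prediction (defaults to the
#'   silver standard's panel).
#' @return List of `location_prediction` objects, one per team.
#' @export
generate_team_ensemble <- function(silver, geometry, n_teams,
                                   corruption = 0, seed = 1L,
                                   gene_panel = silver$gene_panel) {
  stopifnot(inherits(silver, "silver_standard"),
            inherits(geometry, "embryo_geometry"))
  check_scalar_number(n_teams, "n_teams", lower = 1, integer = TRUE)
  check_scalar_number(corruption, "corruption", lower = 0, upper = 1)
  if (length(silver$cells) == 0L) stop_invalid("silver standard is empty")
  nb <- n_bins(geometry)
  seeds <- derive_seeds(seed, n_teams)
  lapply(seq_len(n_teams), function(tm) {
    bins <- silver$reference_list
    if (corruption > 0) {
      bins <- with_seed(seeds[tm], {
        for (ci in seq_len(nrow(bins))) {
          hit <- which(stats::runif(10) < corruption)
          for (j in hit) {
            repeat {
              wrong <- sample.int(nb, 1L)
              if (wrong == silver$epsilon[ci]) next
              hood <- c(wrong, geometry$knn[wrong, ])
              cand <- sample(hood, 1L)
              if (!(cand %in% bins[ci, -j])) {
                bins[ci, j] <- cand
                break
              }
            }
          }
        }
        bins
      })
    }
    location_prediction(bins, cells = silver$cells, gene_panel = gene_panel)
  })
}
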