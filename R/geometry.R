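#' Construct an embryo geometry
#'
#' An `embryo_geometry` holds the spatial substrate of the reconstruction
#' problem: bin identifiers, their 3-D coordinates, and per-bin ordered
#' k-nearest-neighbor lists (Euclidean distance, self excluded, distance
#' ties broken by ascending bin id).
#'
#' @param coords numeric matrix with one row per bin and columns x, y, z.
#' @param k_neighbors number of nearest neighbors to record per bin.
#' @return An object of class `embryo_geometry`: a list with elements
#'   `coords` (n x 3 matrix), `bin_id` (integer vector 1..n), `knn`
#'   (n x k integer matrix, nearest first) and `k_neighbors`.
#' @export
embryo_geometry <- function(coords, k_neighbors = 10L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) {
    stop_invalid("`coords` must have exactly three columns (x, y, z)")
  }
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  n <- nrow(coords)
  check_scalar_number(k_neighbors, "k_neighbors", lower = 1, integer = TRUE)
  if (n <= k_neighbors) {
    stop_invalid("number of bins must exceed `k_neighbors`")
  }
  rownames(coords) <- NULL
  structure(
    list(
      coords = coords,
      bin_id = seq_len(n),
      knn = knn_index(coords, as.integer(k_neighbors)),
      k_neighbors = as.integer(k_neighbors)
    ),
    class = "embryo_geometry"
  )
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat(sprintf("embryo_geometry: %d bins, %d nearest neighbors per bin\n",
              nrow(x$coords), x$k_neighbors))
  invisible(x)
}

n_bins <- function(geometry) nrow(geometry$coords)

# Ordered kNN indices; ties in distance broken by ascending bin id.
knn_index <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))
    out[i, ] <- ord[seq_len(k)]
  }
  out
}

#' Generate a synthetic half-shell embryo geometry
#'
#' Places bins quasi-uniformly on one half (y >= 0) of an ellipsoid shell,
#' mimicking an embryo whose cells sit in a single two-dimensional sheet
#' with bilateral symmetry, so that only one lateral half needs to be
#' modeled. Placement follows a Fibonacci spiral on the ellipsoid with a
#' small seeded angular jitter, giving reproducible, approximately even
#' coverage; points with y < 0 are rejected.
#'
#' @param n_bins number of spatial bins to generate.
#' @param axis_lengths semi-axes (a, b, c) of the ellipsoid. The default
#'   (2, 1, 1) gives the elongated anterior-posterior shape of an insect
#'   embryo.
#' @param k_neighbors neighbors recorded per bin (default 10).
#' @param seed integer seed; distinct seeds give distinct coordinate sets.
#' @return An [embryo_geometry].
#' @export
generate_geometry <- function(n_bins, axis_lengths = c(2, 1, 1),
                              k_neighbors = 10L, seed = 1L) {
  check_scalar_number(n_bins, "n_bins", lower = 2, integer = TRUE)
  check_scalar_number(k_neighbors, "k_neighbors", lower = 1, integer = TRUE)
  if (n_bins <= k_neighbors) {
    stop_invalid("`n_bins` must exceed `k_neighbors`")
  }
  if (length(axis_lengths) != 3L || any(axis_lengths <= 0)) {
    stop_invalid("`axis_lengths` must be three positive reals")
  }
  coords <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    m <- ceiling(2.4 * n_bins)
    pts <- NULL
    golden <- pi * (3 - sqrt(5))
    while (is.null(pts) || nrow(pts) < n_bins) {
      i <- seq_len(m) - 0.5
      z <- 1 - 2 * i / m
      # small seeded jitter keeps seeds distinguishable without harming
      # the even spread
      theta <- i * golden + phase + stats::rnorm(m, sd = 0.01)
      r <- sqrt(pmax(0, 1 - z^2))
      unit <- cbind(r * cos(theta), r * sin(theta), z)
      keep <- unit[, 2] >= 0
      pts <- unit[keep, , drop = FALSE]
      m <- ceiling(m * 1.3)
    }
    pts <- pts[seq_len(n_bins), , drop = FALSE]
    sweep(pts, 2, axis_lengths, `*`)
  })
  embryo_geometry(coords, k_neighbors = k_neighbors)
}

# Euclidean distances from each of `bins` (integer ids) to reference point(s).
bin_distances <- function(geometry, bins, to) {
  d <- geometry$coords[bins, , drop = FALSE] -
    matrix(to, nrow = length(bins), ncol = 3, byrow = TRUE)
  sqrt(rowSums(d^2))
}
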