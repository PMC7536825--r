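#' Construct an ordered location prediction
#'
#' @param bins integer matrix, one row per cell and exactly 10 columns:
#'   the predicted bins, most probable first. Entries within a row must
#'   be distinct.
#' @param cells cell identifiers (row names).
#' @param gene_panel the gene panel the prediction used.
#' @param n_locations number of locations per cell (10 throughout).
#' @return Object of class `location_prediction`.
#' @export
location_prediction <- function(bins, cells = rownames(bins),
                                gene_panel = NULL, n_locations = 10L) {
  bins <- as.matrix(bins)
  if (ncol(bins) != n_locations) {
    stop_invalid(sprintf("each cell needs exactly %d predicted bins",
                         n_locations))
  }
  if (any(bins != round(bins)) || any(bins < 1)) {
    stop_invalid("predicted bins must be positive integer ids")
  }
  storage.mode(bins) <- "integer"
  if (is.null(cells)) cells <- paste0("cell", seq_len(nrow(bins)))
  dup <- apply(bins, 1, anyDuplicated) > 0
  if (any(dup)) {
    stop_invalid("duplicate bin within the prediction of cell(s): ",
                 paste(utils::head(cells[dup], 5), collapse = ", "))
  }
  rownames(bins) <- cells
  structure(list(bins = bins, cells = cells, gene_panel = gene_panel),
            class = "location_prediction")
}

#' @export
print.location_prediction <- function(x, ...) {
  cat(sprintf("location_prediction: %d cells x %d locations (panel: %s genes)\n",
              nrow(x$bins), ncol(x$bins),
              if (is.null(x$gene_panel)) "?" else length(x$gene_panel)))
  invisible(x)
}

#' Matthews correlation coefficient of two binary vectors
#'
#' The phi coefficient of the 2x2 contingency table of `u` and `v`:
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any
#' denominator factor is zero (a constant vector), the MCC is defined as
#' 0: constant profiles carry no information.
#'
#' @param u,v binary vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
mcc <- function(u, v) {
  if (length(u) != length(v)) stop_invalid("`u` and `v` differ in length")
  if (length(u) == 0L) stop_invalid("vectors must be non-empty")
  check_binary(u, "u"); check_binary(v, "v")
  tp <- sum(u == 1 & v == 1)
  tn <- sum(u == 0 & v == 0)
  fp <- sum(u == 0 & v == 1)
  fn <- sum(u == 1 & v == 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# All-pairs MCC between bin atlas profiles and cell profiles, vectorized
# through the 2x2 contingency identities. f: bins x K binary; t: K x cells
# binary. Returns bins x cells matrix; zero-denominator entries are 0.
mcc_matrix <- function(f, t) {
  k <- ncol(f)
  stopifnot(nrow(t) == k)
  tp <- f %*% t
  fb <- rowSums(f)           # ON genes per bin
  ct <- colSums(t)           # ON genes per cell
  fp <- outer(rep(1, nrow(f)), ct) - tp   # t ON, f OFF
  fn <- fb - tp                            # f ON, t OFF
  tn <- k - tp - fp - fn
  num <- tp * tn - fp * fn
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  out <- matrix(0, nrow(f), ncol(t))
  pos <- den > 0
  out[pos] <- num[pos] / sqrt(den[pos])
  out
}

#' Map cells to spatial bins by maximum MCC
#'
#' For each cell, ranks all bins by the MCC between the cell's
#' panel-restricted binarized profile and the bin's panel-restricted
#' atlas profile (descending; exact ties broken by ascending bin id) and
#' returns the `top_n` bins in rank order.
#'
#' @param expr an [expression_matrix] with a `binarized` layer.
#' @param atlas an [insitu_atlas].
#' @param gene_panel genes to use; default all atlas genes.
#' @param top_n locations returned per cell (default 10).
#' @param keep_mcc if `TRUE`, attach the full bins x cells MCC matrix as
#'   attribute `"mcc"`.
#' @param layer expression layer holding the ON/OFF calls (default
#'   `"binarized"`; `"latent"` for noiseless synthetic truth).
#' @return A [location_prediction].
#' @export
map_cells <- function(expr, atlas, gene_panel = atlas$genes, top_n = 10L,
                      keep_mcc = FALSE, layer = "binarized") {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(atlas, "insitu_atlas"))
  check_scalar_number(top_n, "top_n", lower = 1, integer = TRUE)
  if (top_n > nrow(atlas$f)) {
    stop_invalid("`top_n` cannot exceed the number of bins")
  }
  missing_atlas <- setdiff(gene_panel, atlas$genes)
  if (length(missing_atlas)) {
    stop_invalid("panel gene(s) missing from atlas: ",
                 paste(missing_atlas, collapse = ", "))
  }
  missing_expr <- setdiff(gene_panel, expr$genes)
  if (length(missing_expr)) {
    stop_invalid("panel gene(s) missing from expression: ",
                 paste(missing_expr, collapse = ", "))
  }
  t_bin <- get_layer(expr, layer)[gene_panel, , drop = FALSE]
  check_binary(t_bin, layer)
  f <- atlas$f[, gene_panel, drop = FALSE]
  m <- mcc_matrix(f, t_bin)
  nb <- nrow(f)
  top <- apply(m, 2, function(col) order(-col, seq_len(nb))[seq_len(top_n)])
  pred <- location_prediction(t(top), cells = expr$cells,
                              gene_panel = gene_panel, n_locations = top_n)
  if (keep_mcc) attr(pred, "mcc") <- m
  pred
}

#' Build the silver-standard ground truth
#'
#' Maps every cell with the full atlas panel (the analogue of the
#' challenge's 84 in situ genes), takes the top-1 bin as the ground-truth
#' location, keeps the ordered 10-bin reference list, computes the
#' reference distance (mean Euclidean distance of the 10 reference bins
#' to the ground-truth position), and flags a cell ambiguous when two or
#' more bins attain the maximal MCC within 1e-12.
#'
#' @param expr an [expression_matrix] with a binarized (or latent) layer.
#' @param atlas an [insitu_atlas]; all its genes are used.
#' @param geometry the [embryo_geometry].
#' @param layer expression layer holding the ON/OFF calls.
#' @return Object of class `silver_standard` with fields `cells`,
#'   `epsilon`, `reference_list`, `d84_ref`, `ambiguous`, `gene_panel`.
#' @export
build_silver_standard <- function(expr, atlas, geometry,
                                  layer = "binarized") {
  stopifnot(inherits(geometry, "embryo_geometry"))
  pred <- map_cells(expr, atlas, gene_panel = atlas$genes, top_n = 10L,
                    keep_mcc = TRUE, layer = layer)
  m <- attr(pred, "mcc")
  eps <- unname(pred$bins[, 1])
  ambiguous <- vapply(seq_along(eps), function(ci) {
    sum(m[, ci] >= max(m[, ci]) - 1e-12) >= 2L
  }, logical(1))
  d84 <- vapply(seq_along(eps), function(ci) {
    mean(bin_distances(geometry, pred$bins[ci, ], geometry$coords[eps[ci], ]))
  }, numeric(1))
  structure(list(cells = expr$cells, epsilon = eps,
                 reference_list = pred$bins, d84_ref = d84,
                 ambiguous = ambiguous, gene_panel = atlas$genes),
            class = "silver_standard")
}

#' @export
print.silver_standard <- function(x, ...) {
  cat(sprintf("silver_standard: %d cells (%d ambiguous), %d-gene reference panel\n",
              length(x$cells), sum(x$ambiguous), length(x$gene_panel)))
  invisible(x)
}
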