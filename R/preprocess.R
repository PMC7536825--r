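#' Library-size normalize UMI counts
#'
#' Fills the `normalized` layer with
#' `constant * log(pseudocount + scale * raw / total_umi_of_cell)`.
#' The transform is monotone within each cell, so it preserves
#' within-cell rank order; the multiplicative constant only rescales and
#' cannot affect binarization or MCC-based mapping.
#'
#' @param expr an [expression_matrix] with a raw layer; every cell must
#'   have total UMI > 0.
#' @param scale library-size scale factor (default 10,000).
#' @param pseudocount added before the log (default 1, so zero counts map
#'   to 0).
#' @param constant final multiplicative constant (default 1).
#' @return The expression matrix with the `normalized` layer filled.
#' @export
normalize_expression <- function(expr, scale = 1e4, pseudocount = 1,
                                 constant = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  check_scalar_number(scale, "scale")
  check_scalar_number(pseudocount, "pseudocount")
  if (scale <= 0 || pseudocount <= 0) {
    stop_invalid("`scale` and `pseudocount` must be positive")
  }
  totals <- colSums(expr$raw)
  if (any(totals == 0)) {
    stop_invalid("cell(s) with zero total UMI: ",
                 paste(utils::head(expr$cells[totals == 0], 5),
                       collapse = ", "))
  }
  expr$normalized <- constant *
    log(pseudocount + scale * sweep(expr$raw, 2, totals, `/`))
  expr
}

#' Binarize normalized expression at a per-gene quantile
#'
#' For each gene, the ON threshold is the `q`-quantile (linear
#' interpolation between order statistics) of that gene's normalized
#' values over *expressing* cells only (raw count > 0). Cells at or above
#' the threshold are ON; cells with raw count 0 are always OFF. A gene
#' expressed in no cell yields an all-zero column with a warning.
#'
#' @param expr an [expression_matrix] with a normalized layer.
#' @param q quantile in (0, 1).
#' @return The expression matrix with the `binarized` layer filled.
#' @export
binarize_expression <- function(expr, q) {
  stopifnot(inherits(expr, "expression_matrix"))
  check_scalar_number(q, "q")
  if (q <= 0 || q >= 1) stop_invalid("`q` must lie strictly inside (0, 1)")
  norm <- get_layer(expr, "normalized")
  bin <- matrix(0, nrow(norm), ncol(norm))
  silent_genes <- character(0)
  for (g in seq_len(nrow(norm))) {
    expressing <- expr$raw[g, ] > 0
    if (!any(expressing)) {
      silent_genes <- c(silent_genes, expr$genes[g])
      next
    }
    thr <- stats::quantile(norm[g, expressing], q, names = FALSE)
    bin[g, ] <- as.numeric(expressing & norm[g, ] >= thr)
  }
  if (length(silent_genes)) {
    warning("gene(s) expressed in zero cells left all-OFF: ",
            paste(utils::head(silent_genes, 5), collapse = ", "),
            call. = FALSE)
  }
  expr$binarized <- bin
  dimnames(expr$binarized) <- dimnames(expr$raw)
  expr
}

#' Select the binarization quantile by matching correlation structure
#'
#' For each candidate quantile, binarizes the expression, computes the
#' gene-gene Pearson correlation matrix of the binarized expression over
#' cells and of the binary atlas over bins (both restricted to the shared
#' genes), and compares the strict lower triangles by root-mean-square
#' difference. Returns the quantile minimizing that distance; ties go to
#' the smaller quantile. Pairs involving a constant gene vector
#' (undefined correlation) are dropped pairwise.
#'
#' @param expr an [expression_matrix] with a normalized layer.
#' @param atlas an [insitu_atlas].
#' @param shared_genes genes present in both (>= 3).
#' @param grid candidate quantiles in (0, 1); default 0.05 to 0.95 in
#'   steps of 0.01.
#' @return List with `q` (the selected quantile), and `objective` (a data
#'   frame of the grid and its RMS distances).
#' @export
select_binarization_quantile <- function(expr, atlas,
                                         shared_genes =
                                           intersect(expr$genes, atlas$genes),
                                         grid = seq(0.05, 0.95, by = 0.01)) {
  if (length(grid) == 0L) stop_invalid("`grid` must be non-empty")
  if (length(shared_genes) < 3L) {
    stop_invalid("need at least three shared genes")
  }
  cor_atlas <- suppressWarnings(
    stats::cor(atlas$f[, shared_genes, drop = FALSE])
  )
  lower <- lower.tri(cor_atlas)
  obj <- vapply(grid, function(q) {
    b <- binarize_expression(expr, q)
    cor_expr <- suppressWarnings(
      stats::cor(t(b$binarized[shared_genes, , drop = FALSE]))
    )
    diff <- (cor_expr - cor_atlas)[lower]
    diff <- diff[is.finite(diff)]
    if (length(diff) == 0L) return(NA_real_)
    sqrt(mean(diff^2))
  }, numeric(1))
  if (all(is.na(obj))) {
    stop_invalid("correlation distance undefined on the whole grid")
  }
  ord <- order(obj, grid)   # ties toward the smaller quantile
  list(q = grid[ord[1]],
       objective = data.frame(q = grid, rms = obj))
}
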