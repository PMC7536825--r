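#' Construct an expression matrix container
#'
#' Holds the genes x cells UMI counts plus derived layers. Layers always
#' share dimensions and dimnames. The `binarized` layer only exists after
#' [binarize_expression()] (or, for synthetic data, may be set to the
#' generator's latent ON/OFF truth). The raw layer may be absent when a
#' derived layer was loaded from disk on its own.
#'
#' @param raw genes x cells matrix of non-negative integer UMI counts,
#'   or `NULL` if only a derived layer is available.
#' @param genes,cells row/column names; default taken from the first
#'   available layer.
#' @param normalized,binarized,latent optional layers with the same shape.
#' @return Object of class `expression_matrix`.
#' @export
expression_matrix <- function(raw = NULL, genes = NULL, cells = NULL,
                              normalized = NULL, binarized = NULL,
                              latent = NULL) {
  layers <- list(raw = raw, normalized = normalized,
                 binarized = binarized, latent = latent)
  layers <- lapply(layers, function(m) if (is.null(m)) NULL else as.matrix(m))
  present <- !vapply(layers, is.null, logical(1))
  if (!any(present)) stop_invalid("at least one layer is required")
  ref <- layers[[which(present)[1]]]
  genes <- genes %||% rownames(ref) %||% paste0("gene", seq_len(nrow(ref)))
  cells <- cells %||% colnames(ref) %||% paste0("cell", seq_len(ncol(ref)))
  if (anyDuplicated(genes)) stop_invalid("duplicate gene name in expression matrix")
  if (anyDuplicated(cells)) stop_invalid("duplicate cell barcode in expression matrix")
  if (!is.null(layers$raw)) {
    if (any(layers$raw < 0) || any(layers$raw != round(layers$raw))) {
      stop_invalid("raw layer must contain non-negative integer counts")
    }
  }
  if (!is.null(layers$binarized)) check_binary(layers$binarized, "binarized")
  if (!is.null(layers$latent)) check_binary(layers$latent, "latent")
  layers <- lapply(layers, function(m) {
    if (is.null(m)) return(NULL)
    if (!identical(dim(m), dim(ref))) {
      stop_invalid("all layers must share the same dimensions")
    }
    storage.mode(m) <- "double"
    dimnames(m) <- list(genes, cells)
    m
  })
  structure(c(layers, list(genes = genes, cells = cells)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  layers <- names(Filter(Negate(is.null),
                         x[c("raw", "normalized", "binarized", "latent")]))
  cat(sprintf("expression_matrix: %d genes x %d cells [layers: %s]\n",
              length(x$genes), length(x$cells),
              paste(layers, collapse = ", ")))
  invisible(x)
}

get_layer <- function(expr, layer) {
  m <- expr[[layer]]
  if (is.null(m)) {
    stop_invalid(sprintf("expression matrix has no `%s` layer", layer))
  }
  m
}
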