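#' Construct a binarized in situ atlas
#'
#' @param f binary matrix, spatial bins as rows and genes as columns.
#' @param genes gene names; defaults to the column names of `f`.
#' @param pattern optional data frame recording how each synthetic gene
#'   pattern was generated (see [generate_atlas()]).
#' @return Object of class `insitu_atlas` with elements `f`, `genes`,
#'   and optionally `pattern`.
#' @export
insitu_atlas <- function(f, genes = colnames(f), pattern = NULL) {
  f <- as.matrix(f)
  storage.mode(f) <- "double"
  check_binary(f, "f")
  if (is.null(genes)) genes <- paste0("gene", seq_len(ncol(f)))
  if (anyDuplicated(genes)) stop_invalid("atlas gene names must be unique")
  colnames(f) <- genes
  rownames(f) <- NULL
  structure(list(f = f, genes = genes, pattern = pattern),
            class = "insitu_atlas")
}

#' @export
print.insitu_atlas <- function(x, ...) {
  cat(sprintf("insitu_atlas: %d bins x %d genes (ON fraction %.2f)\n",
              nrow(x$f), ncol(x$f), mean(x$f)))
  invisible(x)
}

#' Describe a synthetic spatial expression pattern
#'
#' @param pattern_kind one of `"stripe"`, `"gradient"`, `"patch"`,
#'   `"random"`. Stripes and gradients run along a body axis; patches are
#'   compact spatial clusters; random patterns are spatially uninformative
#'   i.i.d. Bernoulli noise and serve as decoys.
#' @param axis `"x"`, `"y"` or `"z"` (used by stripe and gradient kinds).
#' @param on_fraction target fraction of ON bins, in (0, 1).
#' @param n_units stripe count or patch count.
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(pattern_kind = c("stripe", "gradient", "patch",
                                          "random"),
                         axis = c("x", "y", "z"),
                         on_fraction = 0.3, n_units = 3L) {
  pattern_kind <- match.arg(pattern_kind)
  axis <- match.arg(axis)
  check_scalar_number(on_fraction, "on_fraction")
  if (on_fraction <= 0 || on_fraction >= 1) {
    stop_invalid("`on_fraction` must lie strictly inside (0, 1)")
  }
  check_scalar_number(n_units, "n_units", lower = 1, integer = TRUE)
  structure(list(pattern_kind = pattern_kind, axis = axis,
                 on_fraction = on_fraction, n_units = as.integer(n_units)),
            class = "pattern_spec")
}

#' Generate a spatially patterned binary atlas
#'
#' Builds one binary gene column per pattern specification:
#' * `stripe`: periodic bands along the chosen axis (`n_units` periods,
#'   an ON band of width `on_fraction` per period);
#' * `gradient`: the axis coordinate thresholded at its
#'   `1 - on_fraction` quantile (ON on the high side);
#' * `patch`: union of balls grown around `n_units` random seed bins
#'   until the target ON fraction is reached;
#' * `random`: i.i.d. Bernoulli(`on_fraction`) — no spatial structure.
#'
#' Realized ON fractions are exact up to rounding for gradient and patch,
#' and binomial for random.
#'
#' @param geometry an [embryo_geometry].
#' @param specs list of [pattern_spec()] objects, one per gene.
#' @param seed integer seed.
#' @param gene_names optional gene names (default `g001`, `g002`, ...).
#' @return An [insitu_atlas] whose `pattern` field records each gene's
#'   generating spec.
#' @export
generate_atlas <- function(geometry, specs, seed = 1L, gene_names = NULL) {
  stopifnot(inherits(geometry, "embryo_geometry"))
  if (length(specs) == 0L) stop_invalid("`specs` must contain at least one pattern")
  if (is.null(gene_names)) {
    gene_names <- sprintf("g%03d", seq_along(specs))
  }
  n <- n_bins(geometry)
  seeds <- derive_seeds(seed, length(specs))
  cols <- vapply(seq_along(specs), function(j) {
    spec <- specs[[j]]
    stopifnot(inherits(spec, "pattern_spec"))
    with_seed(seeds[j], pattern_column(geometry, spec))
  }, numeric(n))
  pattern <- data.frame(
    gene = gene_names,
    pattern_kind = vapply(specs, `[[`, "", "pattern_kind"),
    axis = vapply(specs, `[[`, "", "axis"),
    on_fraction = vapply(specs, `[[`, 0, "on_fraction"),
    n_units = vapply(specs, `[[`, 0L, "n_units"),
    stringsAsFactors = FALSE
  )
  insitu_atlas(cols, genes = gene_names, pattern = pattern)
}

pattern_column <- function(geometry, spec) {
  coords <- geometry$coords
  n <- nrow(coords)
  v <- coords[, spec$axis]
  switch(spec$pattern_kind,
    stripe = {
      # n_units periods across the axis range; the leading on_fraction of
      # each period is ON, so the overall ON fraction tracks the target.
      u <- (v - min(v)) / (diff(range(v)) + 1e-12)
      phase <- (u * spec$n_units) %% 1
      as.numeric(phase < spec$on_fraction)
    },
    gradient = {
      thr <- stats::quantile(v, 1 - spec$on_fraction, names = FALSE)
      as.numeric(v >= thr)
    },
    patch = {
      centers <- sample.int(n, spec$n_units)
      # distance of every bin to its nearest patch center; the closest
      # bins form the union of grown balls
      d <- vapply(centers, function(ct) {
        bin_distances(geometry, seq_len(n), geometry$coords[ct, ])
      }, numeric(n))
      dmin <- do.call(pmin, as.data.frame(d))
      on <- order(dmin)[seq_len(max(1L, round(spec$on_fraction * n)))]
      out <- numeric(n)
      out[on] <- 1
      out
    },
    random = as.numeric(stats::runif(n) < spec$on_fraction)
  )
}

#' Default pattern panel for a synthetic atlas
#'
#' Convenience mix of spatially structured genes plus `n_random` random
#' decoys, cycling stripe/gradient/patch kinds over the three axes with
#' varying ON fractions.
#'
#' @param n_genes total number of genes.
#' @param n_random how many of them are spatially random decoys.
#' @return List of [pattern_spec()] objects.
#' @export
default_pattern_panel <- function(n_genes, n_random = 0L) {
  check_scalar_number(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar_number(n_random, "n_random", lower = 0, integer = TRUE)
  if (n_random > n_genes) stop_invalid("`n_random` cannot exceed `n_genes`")
  kinds <- c("stripe", "gradient", "patch")
  axes <- c("x", "y", "z")
  fracs <- c(0.2, 0.3, 0.4, 0.5)
  n_struct <- n_genes - n_random
  specs <- lapply(seq_len(n_struct), function(i) {
    pattern_spec(kinds[(i - 1L) %% 3L + 1L],
                 axis = axes[((i - 1L) %/% 3L) %% 3L + 1L],
                 on_fraction = fracs[(i - 1L) %% 4L + 1L],
                 n_units = (i - 1L) %% 3L + 2L)
  })
  c(specs, lapply(seq_len(n_random), function(i) {
    pattern_spec("random", on_fraction = fracs[(i - 1L) %% 4L + 1L])
  }))
}
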