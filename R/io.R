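# Readers and writers for the on-disk formats: TSV atlas/geometry/
# expression, MatrixMarket sparse counts, the submission dialect, fold
# CSVs, JSON score reports and YAML run configuration. Bin ids are
# 1-based both in files and in memory; this module is the only place
# where file conventions are interpreted.

#' Write the binary atlas and bin coordinates
#'
#' @param atlas an [insitu_atlas].
#' @param geometry the matching [embryo_geometry].
#' @param atlas_path,geometry_path output TSV paths. The atlas is written
#'   bins x genes with a gene-name header; the geometry has columns
#'   x, y, z, one row per bin in atlas order.
#' @export
write_spatial_reference <- function(atlas, geometry, atlas_path,
                                    geometry_path) {
  stopifnot(inherits(atlas, "insitu_atlas"),
            inherits(geometry, "embryo_geometry"))
  utils::write.table(atlas$f, atlas_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(geometry$coords, geometry_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read the binary atlas and bin coordinates
#'
#' Validates that every atlas entry is 0/1 (naming the offending
#' row/column otherwise), that the geometry has x, y and z columns, and
#' that both files agree on the number of bins.
#'
#' @param atlas_path,geometry_path TSV paths as written by
#'   [write_spatial_reference()].
#' @param k_neighbors neighbor count for the reconstructed geometry.
#' @return List with elements `atlas` and `geometry`.
#' @export
read_spatial_reference <- function(atlas_path, geometry_path,
                                   k_neighbors = 10L) {
  a <- utils::read.table(atlas_path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  g <- utils::read.table(geometry_path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  if (!all(c("x", "y", "z") %in% colnames(g))) {
    stop_invalid("geometry file must have x, y and z columns")
  }
  f <- as.matrix(a)
  bad <- which(!(f %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(f)) + 1
    j <- ((bad[1] - 1) %/% nrow(f)) + 1
    stop_invalid(sprintf("non-binary atlas entry at bin %d, gene `%s`",
                         i, colnames(f)[j]))
  }
  if (nrow(f) != nrow(g)) {
    stop_invalid(sprintf(
      "atlas (%d bins) and geometry (%d bins) do not align",
      nrow(f), nrow(g)))
  }
  list(atlas = insitu_atlas(f),
       geometry = embryo_geometry(g[, c("x", "y", "z")],
                                  k_neighbors = k_neighbors))
}

#' Write one expression layer
#'
#' @param expr an [expression_matrix].
#' @param path output path. For `format = "mtx"` this is the MatrixMarket
#'   file; gene and cell names go to `<path>.rows` / `<path>.cols`.
#' @param layer which layer to write.
#' @param format `"tsv"` (genes as rows, first column `gene`, cell
#'   barcodes as header) or `"mtx"` (sparse triplets).
#' @export
write_expression <- function(expr, path,
                             layer = c("raw", "normalized", "binarized"),
                             format = c("tsv", "mtx")) {
  layer <- match.arg(layer)
  format <- match.arg(format)
  m <- get_layer(expr, layer)
  if (format == "tsv") {
    df <- data.frame(gene = expr$genes, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene", expr$cells)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(expr$genes, paste0(path, ".rows"))
    writeLines(expr$cells, paste0(path, ".cols"))
  }
  invisible(NULL)
}

#' Read one expression layer
#'
#' @param path TSV or MatrixMarket path as written by
#'   [write_expression()] (MTX needs the `.rows`/`.cols` side files).
#' @param layer which layer the file holds; a raw layer must be
#'   non-negative integers.
#' @param format `"tsv"` or `"mtx"`.
#' @return An [expression_matrix] with the requested layer filled.
#' @export
read_expression <- function(path,
                            layer = c("raw", "normalized", "binarized"),
                            format = c("tsv", "mtx")) {
  layer <- match.arg(layer)
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    cells <- colnames(m)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(paste0(path, ".rows"))
    cells <- readLines(paste0(path, ".cols"))
    dimnames(m) <- list(genes, cells)
  }
  if (anyDuplicated(genes)) {
    stop_invalid("duplicate gene name: ",
                 genes[duplicated(genes)][1])
  }
  if (layer == "raw" && (any(m < 0) || any(m != round(m)))) {
    stop_invalid("raw counts must be non-negative integers")
  }
  args <- stats::setNames(list(m), layer)
  do.call(expression_matrix,
          c(args, list(genes = genes, cells = cells)))
}

#' Write a location prediction in the submission dialect
#'
#' The dialect is a header line `#genes:` with the comma-separated
#' panel, followed by one TSV row per cell: the cell id and its 10
#' predicted bin ids, best first, 1-based.
#'
#' @param prediction a [location_prediction].
#' @param path output path.
#' @export
write_submission <- function(prediction, path) {
  stopifnot(inherits(prediction, "location_prediction"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#genes: ",
                    paste(prediction$gene_panel, collapse = ",")), con)
  rows <- vapply(seq_along(prediction$cells), function(i) {
    paste(c(prediction$cells[i], prediction$bins[i, ]), collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(NULL)
}

#' Read a submission file
#'
#' Validates the dialect written by [write_submission()]: every row must
#' list exactly 10 distinct bin ids, all valid for the geometry; the
#' order of the 10 bins is preserved (best first).
#'
#' @param path submission file path.
#' @param geometry the [embryo_geometry] the bins must belong to.
#' @return A [location_prediction].
#' @export
read_submission <- function(path, geometry) {
  stopifnot(inherits(geometry, "embryo_geometry"))
  lines <- readLines(path)
  if (length(lines) < 2L || !startsWith(lines[1], "#genes:")) {
    stop_invalid("submission must start with a `#genes:` header line")
  }
  panel <- trimws(strsplit(sub("^#genes:\\s*", "", lines[1]), ",")[[1]])
  panel <- panel[nzchar(panel)]
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  if (any(n_fields != 11L)) {
    stop_invalid(sprintf("row %d has %d bins; exactly 10 are required",
                         which(n_fields != 11L)[1],
                         n_fields[which(n_fields != 11L)[1]] - 1L))
  }
  cells <- vapply(parts, `[[`, "", 1L)
  bins <- t(vapply(parts, function(p) as.integer(p[-1]), integer(10)))
  if (anyNA(bins)) stop_invalid("non-integer bin id in submission")
  if (any(bins < 1L | bins > n_bins(geometry))) {
    stop_invalid("unknown bin id in submission (valid ids are 1..",
                 n_bins(geometry), ")")
  }
  if (anyDuplicated(cells)) {
    stop_invalid("cell listed more than once: ",
                 cells[duplicated(cells)][1])
  }
  location_prediction(bins, cells = cells, gene_panel = panel)
}

#' Write / read a fold assignment
#'
#' Fold assignments travel as two-column CSV (`cell_id`, `fold`).
#'
#' @param folds a data frame with columns `cell` and `fold` (as produced
#'   by [assign_folds()]).
#' @param path CSV path.
#' @export
write_folds <- function(folds, path) {
  utils::write.csv(data.frame(cell_id = folds$cell, fold = folds$fold),
                   path, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' @rdname write_folds
#' @return `read_folds()` returns the fold-assignment data frame.
#' @export
read_folds <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "fold") %in% colnames(df))) {
    stop_invalid("fold file must have cell_id and fold columns")
  }
  data.frame(cell = as.character(df$cell_id), fold = as.integer(df$fold),
             stringsAsFactors = FALSE)
}

#' Write a score report as JSON
#'
#' @param x a `score_triple`, `ranking_result`, or any list of numeric
#'   results.
#' @param path output JSON path.
#' @export
write_score_report <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' Read a YAML run configuration
#'
#' @param path YAML path.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
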