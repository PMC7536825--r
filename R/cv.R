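#' Assign cells to cross-validation folds
#'
#' Seeded uniform partition; fold sizes differ by at most one.
#'
#' @param cells cell identifiers.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return Data frame with columns `cell`, `fold`.
#' @export
assign_folds <- function(cells, n_folds = 10L, seed = 1L) {
  check_scalar_number(n_folds, "n_folds", lower = 1, integer = TRUE)
  if (n_folds > length(cells)) {
    stop_invalid("`n_folds` cannot exceed the number of cells")
  }
  fold <- with_seed(seed, {
    sample(rep(seq_len(n_folds), length.out = length(cells)))
  })
  data.frame(cell = as.character(cells), fold = fold,
             stringsAsFactors = FALSE)
}

#' Simple baseline gene selectors
#'
#' Ranks genes by a statistic computed on the given (training) cells
#' only and returns the top `K`; ties broken by gene name. These
#' selectors stand in for participant methods so the cross-validation
#' loop runs end to end; selecting highly variable genes was among the
#' approaches actually used by challenge teams.
#'
#' @param expr an [expression_matrix] with the layers the criterion
#'   needs (normalized for `variance`/`expression_level`, binarized for
#'   `binarized_entropy`).
#' @param K panel size.
#' @param criterion `"variance"`, `"binarized_entropy"` or
#'   `"expression_level"`.
#' @param cells training cells (default: all).
#' @return Character vector of `K` gene names.
#' @export
baseline_gene_selector <- function(expr, K,
                                   criterion = c("variance",
                                                 "binarized_entropy",
                                                 "expression_level"),
                                   cells = expr$cells) {
  criterion <- match.arg(criterion)
  check_scalar_number(K, "K", lower = 1, integer = TRUE)
  if (K > length(expr$genes)) stop_invalid("`K` exceeds the gene universe")
  stat <- switch(criterion,
    variance = apply(get_layer(expr, "normalized")[, cells, drop = FALSE],
                     1, stats::var),
    binarized_entropy = binary_entropy(
      rowMeans(get_layer(expr, "binarized")[, cells, drop = FALSE])),
    expression_level = rowMeans(
      get_layer(expr, "normalized")[, cells, drop = FALSE])
  )
  expr$genes[order(-stat, expr$genes)][seq_len(K)]
}

#' Expected Jaccard similarity of two random gene panels
#'
#' Exact expectation, by summation over the hypergeometric overlap, of
#' the Jaccard similarity of two independent uniform `K`-subsets of an
#' `n`-gene universe — the chance baseline for fold-to-fold panel
#' stability.
#'
#' @param n size of the gene universe.
#' @param K panel size.
#' @return The expected Jaccard similarity.
#' @export
expected_jaccard_random <- function(n, K) {
  check_scalar_number(n, "n", lower = 1, integer = TRUE)
  check_scalar_number(K, "K", lower = 1, integer = TRUE)
  if (K > n) stop_invalid("`K` cannot exceed `n`")
  i <- 0:K
  sum(stats::dhyper(i, K, n - K, K) * i / (2 * K - i))
}

subset_silver <- function(silver, cells) {
  idx <- match(cells, silver$cells)
  if (anyNA(idx)) stop_invalid("cell(s) absent from the silver standard")
  structure(list(cells = silver$cells[idx],
                 epsilon = silver$epsilon[idx],
                 reference_list = silver$reference_list[idx, , drop = FALSE],
                 d84_ref = silver$d84_ref[idx],
                 ambiguous = silver$ambiguous[idx],
                 gene_panel = silver$gene_panel),
            class = "silver_standard")
}

subset_expression <- function(expr, cells) {
  pick <- function(m) if (is.null(m)) NULL else m[, cells, drop = FALSE]
  expression_matrix(raw = pick(expr$raw), genes = expr$genes,
                    cells = cells, normalized = pick(expr$normalized),
                    binarized = pick(expr$binarized),
                    latent = pick(expr$latent))
}

#' Default configuration of the synthetic CV benchmark
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return Configuration list understood by [run_cv_benchmark()].
#' @export
default_cv_config <- function(seed = 1L) {
  list(
    synthetic = list(n_bins = 500L, n_genes = 60L, n_random_genes = 15L,
                     n_cells = 300L, flip_prob = 0.05, depth_mean = 5000,
                     dropout_midpoint = 0),
    binarize_q = 0.1,
    n_folds = 10L,
    selectors = list(
      list(criterion = "variance", K = 20L),
      list(criterion = "binarized_entropy", K = 20L),
      list(criterion = "expression_level", K = 20L),
      list(criterion = "variance", K = 40L),
      list(criterion = "binarized_entropy", K = 40L)
    ),
    n_boot = 100L,
    include_woc = TRUE,
    seed = as.integer(seed)
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_invalid(sprintf("stage `%s`: %s", stage, conditionMessage(e)))
  })
}

#' Run the synthetic cross-validation benchmark end to end
#'
#' Generates a synthetic embryo (or loads data via config paths),
#' preprocesses it, builds the silver standard from the full gene panel,
#' and runs an `n_folds` cross-validation of the baseline gene
#' selectors: per fold, each selector picks its panel on training cells
#' only, the held-out cells are mapped with that panel, and the fold is
#' scored against the silver standard. Selector-level predictions
#' assembled across folds are then ranked by [bootstrap_rank()], and an
#' optional wisdom-of-crowds consensus of the selectors is scored
#' alongside them. Everything is deterministic under `config$seed`.
#'
#' @param config configuration list (see [default_cv_config()]).
#' @param out_dir optional output directory; when given, per-fold
#'   scores, summaries, the selection-frequency table and a JSON
#'   manifest (config, seeds, file checksums) are written there.
#' @return List with `per_fold`, `summary`, `stability`,
#'   `selection_frequency`, `ranking`, `woc_scores` (or NULL), `folds`.
#' @export
run_cv_benchmark <- function(config = default_cv_config(),
                             out_dir = NULL) {
  seeds <- derive_seeds(config$seed %||% 1L, 6L)
  data <- if (!is.null(config$files)) {
    run_stage("load", {
      for (f in unlist(config$files)) {
        if (!file.exists(f)) stop("file not found: ", f)
      }
      ref <- read_spatial_reference(config$files$atlas,
                                    config$files$geometry)
      list(expr = read_expression(config$files$expression, layer = "raw"),
           geometry = ref$geometry, atlas = ref$atlas)
    })
  } else {
    syn <- config$synthetic
    run_stage("simulate", {
      geometry <- generate_geometry(syn$n_bins, k_neighbors = 10L,
                                    seed = seeds[1])
      specs <- default_pattern_panel(syn$n_genes, syn$n_random_genes)
      atlas <- generate_atlas(geometry, specs, seed = seeds[2])
      truth <- synthetic_truth(flip_prob = syn$flip_prob,
                               depth_mean = syn$depth_mean,
                               dropout_midpoint = syn$dropout_midpoint,
                               seed = seeds[3])
      c(generate_cells(atlas, geometry, syn$n_cells, truth),
        list(geometry = geometry, atlas = atlas))
    })
  }
  expr <- run_stage("preprocess", {
    e <- normalize_expression(data$expr)
    binarize_expression(e, config$binarize_q %||% 0.1)
  })
  silver <- run_stage("silver", {
    build_silver_standard(expr, data$atlas, data$geometry)
  })
  folds <- run_stage("folds", {
    assign_folds(expr$cells, config$n_folds, seed = seeds[4])
  })
  selector_name <- function(s) sprintf("%s_K%d", s$criterion, s$K)
  cv <- run_stage("cv", {
    per_fold <- list()
    panels <- list()
    predictions <- list()
    for (s in config$selectors) {
      sname <- selector_name(s)
      bins <- matrix(NA_integer_, length(expr$cells), 10,
                     dimnames = list(expr$cells, NULL))
      panels[[sname]] <- list()
      for (f in sort(unique(folds$fold))) {
        test_cells <- folds$cell[folds$fold == f]
        train_cells <- folds$cell[folds$fold != f]
        panel <- baseline_gene_selector(expr, s$K, s$criterion,
                                        cells = train_cells)
        panels[[sname]][[f]] <- panel
        pred_f <- map_cells(subset_expression(expr, test_cells),
                            data$atlas, gene_panel = panel)
        bins[test_cells, ] <- pred_f$bins
        silver_f <- subset_silver(silver, test_cells)
        if (any(!silver_f$ambiguous)) {
          sc <- score_submission(pred_f, silver_f, data$atlas,
                                 subset_expression(expr, test_cells),
                                 data$geometry)
          per_fold[[length(per_fold) + 1L]] <-
            data.frame(selector = sname, fold = f, s1 = sc$s1,
                       s2 = sc$s2, s3 = sc$s3, n = sc$n_cells_scored,
                       stringsAsFactors = FALSE)
        }
      }
      # panel attached for gene-wise scoring: the genes most frequently
      # selected across the folds (training-side information only)
      freq <- selection_frequency(panels[[sname]])
      predictions[[sname]] <- location_prediction(
        bins, cells = expr$cells,
        gene_panel = woc_gene_panel(freq, s$K))
    }
    list(per_fold = do.call(rbind, per_fold), panels = panels,
         predictions = predictions)
  })
  summary_df <- run_stage("summarize", {
    do.call(rbind, lapply(split(cv$per_fold, cv$per_fold$selector),
                          function(d) {
      data.frame(selector = d$selector[1],
                 mean_s1 = mean(d$s1), sd_s1 = stats::sd(d$s1),
                 mean_s2 = mean(d$s2), sd_s2 = stats::sd(d$s2),
                 mean_s3 = mean(d$s3), sd_s3 = stats::sd(d$s3),
                 stringsAsFactors = FALSE)
    }))
  })
  stability <- run_stage("stability", {
    do.call(rbind, lapply(names(cv$panels), function(sname) {
      ps <- cv$panels[[sname]]
      pairs <- utils::combn(length(ps), 2)
      jac <- apply(pairs, 2, function(ij) jaccard(ps[[ij[1]]], ps[[ij[2]]]))
      data.frame(selector = sname, mean_jaccard = mean(jac),
                 expected_random = expected_jaccard_random(
                   length(expr$genes), length(ps[[1]])),
                 stringsAsFactors = FALSE)
    }))
  })
  freq_all <- selection_frequency(unlist(cv$panels, recursive = FALSE),
                                  universe = expr$genes)
  ranking <- run_stage("ranking", {
    bootstrap_rank(cv$predictions, silver, data$atlas, expr,
                   data$geometry, n_boot = config$n_boot %||% 100L,
                   seed = seeds[5])
  })
  woc_scores <- NULL
  if (isTRUE(config$include_woc)) {
    woc_scores <- run_stage("woc", {
      cons <- woc_predictions(cv$predictions, data$geometry,
                              consensus_config(seed = seeds[6]),
                              gene_panel = woc_gene_panel(
                                freq_all, config$selectors[[1]]$K))
      score_submission(cons, silver, data$atlas, expr, data$geometry)
    })
  }
  report <- list(per_fold = cv$per_fold, summary = summary_df,
                 stability = stability,
                 selection_frequency = freq_all,
                 ranking = ranking, woc_scores = woc_scores,
                 folds = folds, silver = silver)
  if (!is.null(out_dir)) {
    run_stage("write", write_cv_report(report, config, out_dir))
  }
  report
}

write_cv_report <- function(report, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(per_fold = "per_fold_scores.tsv",
             summary = "score_summary.tsv",
             stability = "panel_stability.tsv",
             selection_frequency = "selection_frequency.tsv")
  for (nm in names(files)) {
    utils::write.table(report[[nm]], file.path(out_dir, files[[nm]]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_folds(report$folds, file.path(out_dir, "folds.csv"))
  manifest <- list(
    config = config,
    mean_rank = as.list(report$ranking$mean_rank),
    woc_scores = if (!is.null(report$woc_scores)) {
      unclass(report$woc_scores)
    },
    files = lapply(stats::setNames(nm = unname(c(files, "folds.csv"))),
                   function(f) {
                     unname(tools::md5sum(file.path(out_dir, f)))
                   })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
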