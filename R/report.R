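#' Round half up for display
#'
#' Tabled accuracies are printed with one decimal, half rounded away from
#' zero (so 83.45 -> 83.5), unlike base R's banker's rounding. Internal
#' values are always kept at full precision.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# population standard deviation (the tabled "std")
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

#' Per-class performance summary of selected feature subsets
#'
#' Re-evaluates each selected subset by LOOCV and tabulates, per class, the
#' mean and population standard deviation of the producer accuracy over the
#' subsets, plus the mean and std of the overall accuracy -- the layout of
#' the published pair-performance tables.
#'
#' @param scaled a [scale_features()] table.
#' @param subsets a `search_result` (e.g. from [select_top_fraction()]) or
#'   list of feature-name vectors.
#' @param spec a [classifier_spec()].
#' @param task `"species"` or `"habit"`.
#' @return data.frame with columns `class`, `mean`, `std` (percent); the
#'   last row, class `"Total"`, summarises the overall accuracies.
#' @export
summarize_pairs <- function(scaled, subsets, spec, task = "species") {
  feats <- pair_list(subsets)
  stopifnot(length(feats) >= 1)
  evals <- lapply(feats, function(s) loocv_evaluate(scaled, s, spec, task))
  producer <- do.call(rbind, lapply(evals, function(e) e$producer))
  overall <- vapply(evals, function(e) e$overall, numeric(1))
  out <- data.frame(
    class = c(colnames(producer), "Total"),
    mean = c(colMeans(producer, na.rm = TRUE), mean(overall)),
    std = c(apply(producer, 2, pop_sd), pop_sd(overall)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Compare four-feature classification strategies
#'
#' Runs the full four-feature protocol on one dataset and reports the five
#' headline accuracies: (A) the best mixed feature quadruple, (B) the mean
#' over all tested quadruples, (C) a forward-selected four-feature set from
#' the structural pool only, (D) the same from the spectral pool only, and
#' (E) a forward-selected mixed set drawing on both pools.
#'
#' @param scaled a [scale_features()] table.
#' @param spec a [classifier_spec()].
#' @param structural_pool,spectral_pool feature column pools.
#' @param task `"species"` or `"habit"`.
#' @param fraction top fraction of pairs kept for quadruple formation.
#' @param max_quadruples cap on evaluated quadruples; when exceeded a
#'   seeded random sample of this size is evaluated instead.
#' @param seed seed for the quadruple subsample.
#' @return named numeric vector `best_quadruple`, `mean_quadruple`,
#'   `forward_structural`, `forward_spectral`, `forward_mixed` (percent),
#'   with attributes `sd_quadruple`, `n_quadruples`, and the two pair-search
#'   results.
#' @export
compare_four_feature_modes <- function(scaled, spec, structural_pool,
                                       spectral_pool, task = "species",
                                       fraction = 0.10,
                                       max_quadruples = Inf, seed = 1L) {
  pairs_str <- exhaustive_search(scaled, structural_pool, 2L, spec, task)
  pairs_spc <- exhaustive_search(scaled, spectral_pool, 2L, spec, task)
  sel_str <- select_top_fraction(pairs_str, fraction)
  sel_spc <- select_top_fraction(pairs_spc, fraction)
  quads <- form_quadruples(sel_str, sel_spc)
  if (length(quads) > max_quadruples) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(seed)
    quads <- quads[sort(sample.int(length(quads), max_quadruples))]
  }
  quad_acc <- vapply(quads, function(s)
    loocv_evaluate(scaled, s, spec, task)$overall, numeric(1))

  fw_str <- forward_select(scaled, structural_pool, 4L, spec, task)
  fw_spc <- forward_select(scaled, spectral_pool, 4L, spec, task)
  fw_mix <- forward_select(scaled, c(structural_pool, spectral_pool), 4L,
                           spec, task)

  out <- c(best_quadruple = max(quad_acc),
           mean_quadruple = mean(quad_acc),
           forward_structural = fw_str$accuracy,
           forward_spectral = fw_spc$accuracy,
           forward_mixed = fw_mix$accuracy)
  attr(out, "sd_quadruple") <- pop_sd(quad_acc)
  attr(out, "n_quadruples") <- length(quads)
  attr(out, "pairs_structural") <- pairs_str
  attr(out, "pairs_spectral") <- pairs_spc
  out
}

#' Bar plot of the four-feature strategy comparison
#'
#' @param modes result of [compare_four_feature_modes()].
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the bar midpoints.
#' @export
plot_four_feature_modes <- function(modes, ...) {
  graphics::barplot(as.numeric(modes),
                    names.arg = c("A best quad", "B mean quad",
                                  "C fwd struct", "D fwd spect",
                                  "E fwd mixed"),
                    ylab = "Overall LOOCV accuracy (%)", ylim = c(0, 100),
                    ...)
}

#' Write a search result as CSV
#'
#' Columns `subset,accuracy,n_eval` (ranked).
#'
#' @param result a `search_result`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_search_csv <- function(result, path) {
  df <- data.frame(subset = result$subset, accuracy = result$accuracy,
                   n_eval = attr(result, "n_evaluated"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Classification run manifest
#'
#' Records everything needed to reproduce a classification run: dataset
#' sizes, feature pools, classifier grids, selection fraction and seed.
#'
#' @param scaled a [scale_features()] table.
#' @param spec a [classifier_spec()].
#' @param extra named list merged into the manifest (e.g. scene seed,
#'   pools, fraction).
#' @param path optional path; when given the manifest is written as JSON.
#' @return the manifest list, invisibly when written.
#' @export
run_manifest <- function(scaled, spec, extra = list(), path = NULL) {
  manifest <- c(list(
    package = "canopyfuse",
    version = as.character(utils::packageVersion("canopyfuse")),
    n_specimens = nrow(scaled),
    n_features = length(feature_columns(scaled)),
    scaling_mode = attr(scaled, "scaling_mode"),
    family = spec$family,
    C_grid = spec$C_grid, gamma_grid = spec$gamma_grid,
    inner_folds = spec$folds, seed = spec$seed), extra)
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               path)
    return(invisible(manifest))
  }
  manifest
}
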