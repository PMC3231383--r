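#' Classifier specification
#'
#' Bundles the classifier family and its tuning protocol. For the RBF-kernel
#' SVM the (C, gamma) point is chosen by seeded stratified inner
#' cross-validation over the grid; a grid with a single point disables
#' tuning. The coarse default grid is a 3 x 3 subset of the standard
#' exponential search grid C in 2^(-5..15), gamma in 2^(-15..3); the full
#' grid is available with `grid = "full"`.
#'
#' @param family `"svm_rbf"` or `"lda"` (grids are ignored for LDA).
#' @param C_grid,gamma_grid positive numeric grids; `NULL` uses the preset.
#' @param folds inner-CV folds for tuning.
#' @param seed integer; all inner-CV shuffles derive from it. LOOCV itself
#'   has no randomness.
#' @param grid `"coarse"` (default) or `"full"` preset.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm_rbf", "lda"),
                            C_grid = NULL, gamma_grid = NULL,
                            folds = 5L, seed = 1L,
                            grid = c("coarse", "full")) {
  family <- match.arg(family)
  grid <- match.arg(grid)
  if (family == "svm_rbf") {
    if (is.null(C_grid))
      C_grid <- if (grid == "coarse") 2^c(-1, 5, 11) else 2^seq(-5, 15, 2)
    if (is.null(gamma_grid))
      gamma_grid <- if (grid == "coarse") 2^c(-9, -3, 3) else 2^seq(-15, 3, 2)
    stopifnot(length(C_grid) > 0, all(C_grid > 0),
              length(gamma_grid) > 0, all(gamma_grid > 0))
  }
  structure(list(family = family, C_grid = C_grid, gamma_grid = gamma_grid,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "classifier_spec")
}

feature_columns <- function(table) {
  setdiff(names(table), c("specimen_id", "species", "habit"))
}

task_labels <- function(table, task = c("species", "habit")) {
  task <- match.arg(task)
  factor(table[[task]])
}

#' Scale features to \[-1, 1\]
#'
#' Linear min-max scaling `x' = 2 (x - min) / (max - min) - 1` per feature;
#' constant features map to 0. `mode = "global"` scales once on all data
#' before classification (the protocol-faithful default); `mode =
#' "per_fold"` defers scaling so every evaluation refits the scaling on its
#' training fold only (the leakage-safe alternative).
#'
#' @param table a `feature_table`.
#' @param mode `"global"` or `"per_fold"`.
#' @param columns feature columns to scale; default all.
#' @return the table with class `scaled_feature_table`; attributes
#'   `scaling` (per-feature min/max) and `scaling_mode`.
#' @export
scale_features <- function(table, mode = c("global", "per_fold"),
                           columns = NULL) {
  mode <- match.arg(mode)
  if (is.null(columns)) columns <- feature_columns(table)
  mins <- vapply(columns, function(cl) suppressWarnings(
    min(table[[cl]], na.rm = TRUE)), numeric(1))
  maxs <- vapply(columns, function(cl) suppressWarnings(
    max(table[[cl]], na.rm = TRUE)), numeric(1))
  if (mode == "global") {
    for (j in seq_along(columns)) {
      x <- table[[columns[j]]]
      table[[columns[j]]] <- scale_minmax(x, mins[j], maxs[j])
    }
  }
  structure(table,
            class = unique(c("scaled_feature_table", class(table))),
            scaling = data.frame(feature = columns, min = mins, max = maxs,
                                 row.names = NULL),
            scaling_mode = mode)
}

scale_minmax <- function(x, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || hi == lo)
    return(ifelse(is.na(x), NA_real_, 0))
  2 * (x - lo) / (hi - lo) - 1
}

# deterministic seeded stratified fold assignment
stratified_folds <- function(y, k, seed) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  folds <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

svm_predict_fold <- function(Xtr, ytr_int, Xte, k, C, gamma) {
  .svm_fit_predict_cpp(Xtr, as.integer(ytr_int), Xte, as.integer(k),
                       C, gamma)
}

lda_predict_fold <- function(Xtr, ytr, Xte, levels_all) {
  ytr <- droplevels(ytr)
  if (nlevels(ytr) < 2L)
    return(factor(rep(levels(ytr), nrow(Xte)), levels = levels_all))
  fit <- suppressWarnings(MASS::lda(Xtr, grouping = ytr))
  pred <- predict(fit, Xte)$class
  factor(as.character(pred), levels = levels_all)
}

extract_design <- function(scaled, subset) {
  missing_cols <- setdiff(subset, names(scaled))
  if (length(missing_cols) > 0)
    stop("unknown feature column(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(as.data.frame(scaled)[, subset, drop = FALSE])
  if (anyNA(X))
    stop("missing values in selected feature columns; drop specimens ",
         "without fused spectra or restrict the feature pool")
  storage.mode(X) <- "double"
  X
}

#' Tune the RBF-SVM kernel parameters
#'
#' Seeded stratified k-fold cross-validation over the spec's (C, gamma)
#' grid; returns the grid point with the highest CV accuracy, ties broken
#' by smallest C then smallest gamma.
#'
#' @param scaled a [scale_features()] table.
#' @param subset character vector of feature columns.
#' @param spec a [classifier_spec()] with family `"svm_rbf"`.
#' @param task `"species"` or `"habit"`.
#' @return named numeric `c(C, gamma, cv_accuracy)`.
#' @export
tune_rbf <- function(scaled, subset, spec, task = "species") {
  stopifnot(inherits(spec, "classifier_spec"), spec$family == "svm_rbf")
  X <- extract_design(scaled, subset)
  y <- task_labels(scaled, task)
  k <- nlevels(y)
  y_int <- as.integer(y)
  folds <- stratified_folds(y, spec$folds, spec$seed)
  grid <- expand.grid(C = sort(spec$C_grid), gamma = sort(spec$gamma_grid))
  per_fold <- identical(attr(scaled, "scaling_mode"), "per_fold")

  acc <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in sort(unique(folds))) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]
      Xte <- X[!tr, , drop = FALSE]
      if (per_fold) {
        sc <- refit_scaling(Xtr, Xte)
        Xtr <- sc$train; Xte <- sc$test
      }
      pred <- svm_predict_fold(Xtr, y_int[tr], Xte, k,
                               grid$C[g], grid$gamma[g])
      correct <- correct + sum(pred == y_int[!tr])
    }
    acc[g] <- correct / length(y)
  }
  best <- order(-acc, grid$C, grid$gamma)[1]
  c(C = grid$C[best], gamma = grid$gamma[best], cv_accuracy = acc[best])
}

refit_scaling <- function(Xtr, Xte) {
  for (j in seq_len(ncol(Xtr))) {
    lo <- min(Xtr[, j]); hi <- max(Xtr[, j])
    Xtr[, j] <- scale_minmax(Xtr[, j], lo, hi)
    Xte[, j] <- scale_minmax(Xte[, j], lo, hi)
  }
  list(train = Xtr, test = Xte)
}

#' Leave-one-out evaluation of a feature subset
#'
#' Each specimen is classified by a model trained on all other specimens;
#' held-out predictions are accumulated into a confusion matrix (rows
#' predicted, columns reference). For the SVM family the kernel parameters
#' are tuned once per subset by [tune_rbf()] when the spec's grid has more
#' than one point. Note that a class with a single specimen can never be
#' predicted correctly under LOOCV (its only member is absent from
#' training), which is what motivates the five-specimen species threshold.
#'
#' @param scaled a [scale_features()] table.
#' @param subset character vector of feature columns.
#' @param spec a [classifier_spec()].
#' @param task `"species"` or `"habit"`.
#' @return an object of class `evaluation_result`: `subset`, `task`,
#'   `family`, `params`, `predicted`, `reference`, `confusion`, `overall`
#'   (percent), `user`, `producer`.
#' @export
loocv_evaluate <- function(scaled, subset, spec, task = "species") {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- extract_design(scaled, subset)
  y <- droplevels(task_labels(scaled, task))
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  n <- nrow(X)
  k <- nlevels(y)
  y_int <- as.integer(y)
  per_fold <- identical(attr(scaled, "scaling_mode"), "per_fold")

  params <- NULL
  if (spec$family == "svm_rbf") {
    if (length(spec$C_grid) * length(spec$gamma_grid) > 1L) {
      params <- tune_rbf(scaled, subset, spec, task)
    } else {
      params <- c(C = spec$C_grid[1], gamma = spec$gamma_grid[1],
                  cv_accuracy = NA_real_)
    }
  }

  if (spec$family == "svm_rbf" && !per_fold) {
    pred_int <- .svm_loocv_cpp(X, y_int, k, params[["C"]],
                               params[["gamma"]])
    predicted <- factor(levels(y)[pred_int], levels = levels(y))
  } else {
    predicted <- factor(rep(NA_character_, n), levels = levels(y))
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]
      Xte <- X[i, , drop = FALSE]
      if (per_fold) {
        sc <- refit_scaling(Xtr, Xte)
        Xtr <- sc$train; Xte <- sc$test
      }
      if (spec$family == "svm_rbf") {
        p <- svm_predict_fold(Xtr, y_int[-i], Xte, k, params[["C"]],
                              params[["gamma"]])
        predicted[i] <- levels(y)[p]
      } else {
        predicted[i] <- lda_predict_fold(Xtr, y[-i], Xte, levels(y))
      }
    }
  }

  confusion <- table(predicted = predicted, reference = y)
  cs <- confusion_summary(confusion)
  structure(list(subset = subset, task = task, family = spec$family,
                 params = params, predicted = predicted, reference = y,
                 confusion = confusion, overall = cs$overall,
                 user = cs$user, producer = cs$producer),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s | %s on '%s': overall %.1f%% (n = %d)\n",
              paste(x$subset, collapse = " + "), x$family, x$task,
              x$overall, length(x$reference)))
  invisible(x)
}

#' Confusion-matrix accuracy summary
#'
#' Overall accuracy is `100 * trace / total`; user accuracy of a class is
#' its diagonal cell over its row (predicted) sum; producer accuracy over
#' its column (reference) sum. Zero rows or columns give `NA` (undefined).
#' All values are percentages at full precision; round for display with
#' [round_half_up()].
#'
#' @param m square non-negative confusion matrix, rows predicted, columns
#'   reference.
#' @return list with `overall`, `user`, `producer`.
#' @export
confusion_summary <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  total <- sum(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  d <- diag(m)
  user <- ifelse(rs > 0, 100 * d / rs, NA_real_)
  producer <- ifelse(cs > 0, 100 * d / cs, NA_real_)
  names(user) <- rownames(m)
  names(producer) <- colnames(m)
  list(overall = 100 * sum(d) / total, user = user, producer = producer)
}

#' Exhaustive single / pair feature search
#'
#' Evaluates every unordered combination of `arity` features from the pool
#' by [loocv_evaluate()]. The result is independent of pool order: rows are
#' sorted by accuracy (non-increasing) with lexicographic subset names as
#' the tie order, so tied subsets sit adjacently.
#'
#' @param scaled a [scale_features()] table.
#' @param pool character vector of candidate feature columns.
#' @param arity subset size, 1 or 2.
#' @param spec a [classifier_spec()].
#' @param task `"species"` or `"habit"`.
#' @param keep_evaluations logical; retain each `evaluation_result` (memory
#'   heavy for large pools).
#' @return an object of class `search_result`: a data.frame with columns
#'   `subset` and `accuracy` (percent), attribute `features` (list of
#'   feature-name vectors in row order) and optionally `evaluations`.
#' @export
exhaustive_search <- function(scaled, pool, arity = 2L, spec,
                              task = "species", keep_evaluations = FALSE) {
  stopifnot(arity %in% c(1L, 2L), length(pool) >= arity)
  combos <- combn(pool, arity, simplify = FALSE)
  combos <- lapply(combos, sort)   # canonical order: results pool-order free
  evals <- lapply(combos, function(s) loocv_evaluate(scaled, s, spec, task))
  acc <- vapply(evals, function(e) e$overall, numeric(1))
  nm <- vapply(combos, paste, character(1), collapse = " + ")
  ord <- order(-acc, nm)
  out <- data.frame(subset = nm[ord], accuracy = acc[ord],
                    stringsAsFactors = FALSE)
  structure(out, class = c("search_result", "data.frame"),
            features = combos[ord],
            evaluations = if (keep_evaluations) evals[ord] else NULL,
            n_evaluated = length(combos), arity = arity, task = task)
}

#' Select the best-performing fraction of a search result
#'
#' The nominal cutoff is `k = ceiling(fraction * N)` subsets; every subset
#' tying the k-th subset's accuracy is also included, so the realized
#' fraction can exceed the nominal one.
#'
#' @param result a `search_result`.
#' @param fraction nominal fraction, default 0.10.
#' @return a `search_result` restricted to the selection, with attributes
#'   `n_selected`, `fraction_nominal` and `fraction_realized_pct`
#'   (percentage, one decimal, round half up).
#' @export
select_top_fraction <- function(result, fraction = 0.10) {
  stopifnot(inherits(result, "search_result"), nrow(result) > 0,
            fraction > 0, fraction <= 1)
  n <- nrow(result)
  k <- ceiling(fraction * n)
  cutoff <- result$accuracy[k]
  sel <- which(result$accuracy >= cutoff)
  out <- result[sel, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("search_result", "data.frame"),
            features = attr(result, "features")[sel],
            n_evaluated = attr(result, "n_evaluated"),
            arity = attr(result, "arity"), task = attr(result, "task"),
            n_selected = length(sel), fraction_nominal = fraction,
            fraction_realized_pct = round_half_up(100 * length(sel) / n, 1))
}

#' Form mixed feature quadruples
#'
#' Cartesian product of a set of structural feature pairs and a set of
#' spectral feature pairs: every quadruple is one shape pair plus one
#' spectral pair, so with disjoint pools all `|A| x |B|` quadruples are
#' unique.
#'
#' @param structural_pairs,spectral_pairs `search_result` objects or lists
#'   of 2-element character vectors.
#' @return list of 4-element character vectors.
#' @export
form_quadruples <- function(structural_pairs, spectral_pairs) {
  a <- pair_list(structural_pairs)
  b <- pair_list(spectral_pairs)
  if (length(a) == 0L || length(b) == 0L) return(list())
  out <- vector("list", length(a) * length(b))
  idx <- 1L
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      out[[idx]] <- c(a[[i]], b[[j]])
      idx <- idx + 1L
    }
  }
  out
}

pair_list <- function(x) {
  if (inherits(x, "search_result")) return(attr(x, "features"))
  stopifnot(is.list(x))
  x
}

#' Greedy forward feature selection
#'
#' Locks the best single feature, then at each iteration adds the feature
#' whose addition gives the highest LOOCV accuracy (ties broken by feature
#' name), for a fixed number of iterations regardless of whether the
#' accuracy improves.
#'
#' @param scaled a [scale_features()] table.
#' @param pool candidate feature columns.
#' @param target_size number of features to select (default 4).
#' @param spec a [classifier_spec()].
#' @param task `"species"` or `"habit"`.
#' @return list with `features` (in selection order), `accuracy` (final
#'   LOOCV accuracy, percent) and `history` (best accuracy per iteration).
#' @export
forward_select <- function(scaled, pool, target_size = 4L, spec,
                           task = "species") {
  stopifnot(length(pool) >= target_size)
  selected <- character(0)
  history <- numeric(0)
  for (iter in seq_len(target_size)) {
    candidates <- sort(setdiff(pool, selected))
    acc <- vapply(candidates, function(f)
      loocv_evaluate(scaled, c(selected, f), spec, task)$overall,
      numeric(1))
    best <- candidates[order(-acc, candidates)[1]]
    selected <- c(selected, best)
    history <- c(history, max(acc))
  }
  list(features = selected, accuracy = history[length(history)],
       history = history)
}
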