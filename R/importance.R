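# Random-forest indicator screening
#
# One RF classifier per species separates nesting (1) from non-nesting (0)
# Coastgons; normalized feature importances rank the 22 indicators,
# performance is evaluated on the training rows themselves (the screening
# protocol; optimistic by construction), robustness is checked by 4-fold
# cross-validation, and a six-indicator subset is selected greedily under a
# collinearity cut.

#' Random-forest configuration
#'
#' @param n_trees Number of trees.
#' @param mtry Features per split (`NULL` = floor(sqrt(p))).
#' @param importance_type `"impurity"` (normalized mean decrease in node
#'   impurity, default) or `"permutation"` (mean decrease in accuracy,
#'   negative values clamped to 0 before normalization).
#' @param class_balance Weight classes inversely to their frequency
#'   (nesting prevalence is typically well below 50%).
#' @param seed Integer seed for the forest (and the CV partition).
#' @return An `importance_config` list.
#' @export
importance_config <- function(n_trees = 500, mtry = NULL,
                              importance_type = c("impurity", "permutation"),
                              class_balance = TRUE, seed = 1) {
  importance_type <- match.arg(importance_type)
  structure(list(n_trees = n_trees, mtry = mtry,
                 importance_type = importance_type,
                 class_balance = class_balance, seed = as.integer(seed)),
            class = "importance_config")
}

rf_design <- function(table, species, indicators = INDICATOR_NAMES) {
  col <- paste0("nesting_", species)
  if (!col %in% names(table)) {
    stop(sprintf("no nesting flags for species '%s' in the table", species))
  }
  x <- as.matrix(table[, indicators, drop = FALSE])
  keep <- stats::complete.cases(x) & apply(is.finite(x), 1, all)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("dropping %d row(s) with missing indicator values", n_dropped))
  }
  x <- x[keep, , drop = FALSE]
  y <- factor(table[[col]][keep], levels = c(0, 1))
  if (sum(y == 1) == 0) stop(sprintf("species '%s' has zero nesting rows", species))
  if (sum(y == 0) == 0) stop(sprintf("species '%s' has zero non-nesting rows", species))
  list(x = x, y = y, keep = keep, n_dropped = n_dropped)
}

fit_rf <- function(x, y, config) {
  mtry <- if (is.null(config$mtry)) max(1, floor(sqrt(ncol(x)))) else config$mtry
  classwt <- if (config$class_balance) {
    w <- 1 / table(y)
    as.numeric(w / sum(w))
  } else NULL
  randomForest::randomForest(
    x = x, y = y, ntree = config$n_trees, mtry = mtry, classwt = classwt,
    importance = config$importance_type == "permutation")
}

importance_from_fit <- function(fit, config) {
  imp <- if (config$importance_type == "permutation") {
    pmax(randomForest::importance(fit, type = 1, scale = FALSE)[, 1], 0)
  } else {
    randomForest::importance(fit, type = 2)[, 1]
  }
  total <- sum(imp)
  if (total <= 0) imp[] <- 1 / length(imp) else imp <- imp / total
  ranks <- stats::setNames(seq_along(imp), names(sort(imp, decreasing = TRUE)))
  ranks <- ranks[names(imp)]
  list(importance = imp, ranks = ranks)
}

#' Fit a random forest and rank indicator importance
#'
#' Fits one RF on all rows (NaN rows dropped listwise), returns relative
#' feature importances (non-negative, summing to 1) with ranks, and
#' precision/recall/F1 computed by predicting the training rows themselves —
#' an intentionally optimistic protocol, used here for screening, not for
#' out-of-sample claims.
#'
#' @param table Indicator table with `nesting_<species>` flags.
#' @param species Species code.
#' @param config An [importance_config()].
#' @param indicators Indicator columns to use.
#' @return An `importance_result`: list with `species`, `importance`,
#'   `ranks`, `scores` (precision/recall/F1), `n_dropped`, `config`.
#' @export
fit_importance <- function(table, species, config = importance_config(),
                           indicators = indicator_names()) {
  d <- rf_design(table, species, indicators)
  set.seed(config$seed)
  fit <- fit_rf(d$x, d$y, config)
  imp <- importance_from_fit(fit, config)
  pred <- stats::predict(fit, d$x)
  tp <- sum(pred == "1" & d$y == "1")
  fp <- sum(pred == "1" & d$y == "0")
  fn <- sum(pred == "0" & d$y == "1")
  structure(list(species = species, importance = imp$importance,
                 ranks = imp$ranks,
                 scores = scores_from_confusion(tp, fp, fn),
                 n_dropped = d$n_dropped, config = config),
            class = "importance_result")
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`, `F1 = 2PR/(P+R)`;
#' zero denominators give 0 with a warning.
#'
#' @param tp,fp,fn True positive, false positive, false negative counts.
#' @return Named numeric vector `precision`, `recall`, `F1`.
#' @export
scores_from_confusion <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) {
    warning("no positive predictions; precision set to 0"); 0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) {
    warning("no positive labels; recall set to 0"); 0
  } else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  c(precision = precision, recall = recall, F1 = f1)
}

#' 4-fold cross-validation of the importance ranking
#'
#' Rows are partitioned at random (seeded) into four equal folds; four
#' sub-models are trained, each on three folds (75% of the rows), and each
#' sub-model's importances are compared with the full model's by Spearman
#' rank correlation.
#'
#' @param table Indicator table with nesting flags.
#' @param species Species code.
#' @param config An [importance_config()].
#' @param indicators Indicator columns to use.
#' @param n_folds Number of folds.
#' @return A `cv_report`: list with `folds` (per-fold importance vectors),
#'   `fold_of` (fold label per retained row), and `consistency` (per-fold
#'   Spearman correlation against the full model).
#' @export
cross_validate <- function(table, species, config = importance_config(),
                           indicators = indicator_names(), n_folds = 4) {
  d <- rf_design(table, species, indicators)
  n <- nrow(d$x)
  if (n < 2 * n_folds) stop("too few rows for cross-validation")
  full <- fit_importance(table, species, config, indicators)
  set.seed(config$seed + 1L)
  fold <- sample(rep(seq_len(n_folds), length.out = n))
  folds <- list()
  consistency <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    idx <- fold != f
    set.seed(config$seed + 1L + f)
    fit <- fit_rf(d$x[idx, , drop = FALSE], droplevels(d$y[idx]), config)
    imp <- importance_from_fit(fit, config)$importance
    folds[[f]] <- imp
    consistency[f] <- spearman_rho(imp, full$importance)
  }
  structure(list(species = species, folds = folds, fold_of = fold,
                 consistency = consistency, full = full),
            class = "cv_report")
}

#' Select an indicator subset by importance under a collinearity cut
#'
#' Walks indicators by descending importance, skipping any whose absolute
#' Spearman correlation with an already-selected indicator meets the cut,
#' stopping at `n`. An explicit `override` list (encoding expert judgment)
#' replaces the automatic choice verbatim and is recorded in the result.
#'
#' @param importance An `importance_result` (or named importance vector).
#' @param corr Spearman correlation matrix of the indicators over Coastgons
#'   (see [stats::cor()] with `method = "spearman"`,
#'   `use = "pairwise.complete.obs"`).
#' @param n Number of indicators to select.
#' @param collinearity_cut Absolute-correlation threshold (inclusive).
#' @param override Optional character vector replacing the automatic choice.
#' @return Character vector of selected indicators, with attribute
#'   `selection` = `"override"` or `"automatic"`.
#' @export
select_indicators <- function(importance, corr, n = 6,
                              collinearity_cut = 0.9, override = NULL) {
  imp <- if (inherits(importance, "importance_result")) {
    importance$importance
  } else importance
  if (!is.null(override)) {
    bad <- setdiff(override, names(imp))
    if (length(bad)) {
      stop(sprintf("override names not in the importance vector: %s",
                   paste(bad, collapse = ", ")))
    }
    return(structure(override, selection = "override"))
  }
  ord <- names(sort(imp, decreasing = TRUE))
  sel <- character(0)
  for (ind in ord) {
    if (length(sel) >= n) break
    if (length(sel) > 0) {
      rho <- abs(corr[ind, sel])
      if (any(is.finite(rho) & rho >= collinearity_cut)) next
    }
    sel <- c(sel, ind)
  }
  if (length(sel) < n) {
    warning(sprintf("only %d indicator(s) selectable under the collinearity cut",
                    length(sel)))
  }
  structure(sel, selection = "automatic")
}
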