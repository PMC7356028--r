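# R interface to the bundled random-forest implementation.

#' Fit a random forest for binary classification
#'
#' Bagged CART trees with gini splits and per-node feature subsampling.
#' Reproducible under `seed` (uses R's RNG). `max_features` follows the
#' usual conventions: `"sqrt"`, a fraction in (0, 1], or an integer count.
#'
#' @param x numeric feature matrix (rows = samples).
#' @param y binary labels (0/1).
#' @param num_trees number of trees (default 300).
#' @param max_features per-node feature subsample rule (default `"sqrt"`).
#' @param max_depth maximum tree depth, 0 = unlimited (default 0).
#' @param min_node minimum samples per leaf (default 1).
#' @param seed RNG seed, or `NULL` to use the current stream.
#' @return An `rf_model`: list with `trees`, `importance` (mean decrease in
#'   impurity, normalized to sum 1), `feature_names`, and the
#'   hyperparameters.
#' @export
rf_fit <- function(x, y, num_trees = 300L, max_features = "sqrt",
                   max_depth = 0L, min_node = 1L, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop_ppiface("labels must be 0/1")
  if (length(unique(y)) < 2L) stop_ppiface("training data has a single class")
  p <- ncol(x)
  mtry <- if (identical(max_features, "sqrt")) max(1L, floor(sqrt(p)))
          else if (is.numeric(max_features) && max_features <= 1)
            max(1L, floor(max_features * p))
          else as.integer(max_features)
  fit <- with_seed(seed,
    rf_fit_cpp(x, y, as.integer(num_trees), as.integer(mtry),
               as.integer(max_depth), as.integer(min_node)))
  imp <- fit$importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(list(trees = fit$trees, importance = imp,
                 feature_names = colnames(x),
                 num_trees = as.integer(num_trees), mtry = mtry,
                 max_depth = as.integer(max_depth),
                 min_node = as.integer(min_node), seed = seed),
            class = "rf_model")
}

#' Predict positive-class probabilities
#'
#' @param model an `rf_model`.
#' @param x feature matrix with the training columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
rf_predict <- function(model, x) {
  stopifnot(inherits(model, "rf_model"))
  x <- as.matrix(x)
  if (!is.null(model$feature_names)) {
    if (is.null(colnames(x)) || !all(model$feature_names %in% colnames(x)))
      stop_ppiface("prediction data missing feature(s): %s",
                   paste(setdiff(model$feature_names, colnames(x)),
                         collapse = ", "))
    x <- x[, model$feature_names, drop = FALSE]
  }
  storage.mode(x) <- "double"
  rf_predict_cpp(model$trees, x)
}
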