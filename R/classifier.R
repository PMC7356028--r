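# Training-table assembly, majority down-sampling, grid-searched random
# forest, evaluation, leave-one-out cross-validation, feature importance.

#' Flatten a feature stack and labels into a training table
#'
#' One row per residue pair (column-major over the M x N grid), with the
#' feature columns in canonical order, the binary label, the complex id
#' and the pair indices.
#'
#' @param stack an 18-feature `feature_stack` (9-feature stacks are
#'   accepted for feature-ablation runs).
#' @param labels a `pair_label_set` over the same grid.
#' @param complex_id identifier stored in the `complex_id` column.
#' @return data.frame with attribute `features` naming the feature columns.
#' @export
build_training_table <- function(stack, labels, complex_id = "complex") {
  stopifnot(inherits(stack, "feature_stack"),
            inherits(labels, "pair_label_set"))
  M <- attr(stack, "M"); N <- attr(stack, "N")
  if (labels$M != M || labels$N != N)
    stop_ppiface("labels are %dx%d but stack is %dx%d",
                 labels$M, labels$N, M, N)
  df <- data.frame(complex_id = complex_id,
                   i = rep(seq_len(M), times = N),
                   j = rep(seq_len(N), each = M))
  for (f in names(stack)) df[[f]] <- as.vector(stack[[f]])
  df$label <- as.vector(label_matrix(labels))
  if (anyNA(df)) stop_ppiface("missing values in training table")
  attr(df, "features") <- names(stack)
  df
}

.table_features <- function(table) {
  attr(table, "features") %||%
    setdiff(names(table), c("complex_id", "i", "j", "label"))
}

#' Down-sample the majority (negative) class
#'
#' Keeps every positive row; negatives are sampled uniformly without
#' replacement down to `ratio` times the positive count (all negatives are
#' kept when fewer are available). Deterministic under `seed`.
#'
#' @param table training table from [build_training_table()].
#' @param ratio negatives per positive (default 5).
#' @param seed RNG seed.
#' @return Down-sampled training table (row order: positives then sampled
#'   negatives).
#' @export
downsample_majority <- function(table, ratio = 5, seed = NULL) {
  pos <- which(table$label == 1L)
  neg <- which(table$label == 0L)
  if (length(pos) == 0L) stop_ppiface("no positive rows to anchor sampling")
  k <- min(length(neg), ceiling(ratio * length(pos)))
  keep_neg <- with_seed(seed, sample(neg, k))
  out <- table[c(pos, sort(keep_neg)), ]
  rownames(out) <- NULL
  attr(out, "features") <- .table_features(table)
  out
}

#' Default hyperparameter grid
#'
#' Trees in \{100, 300, 500\}, depth \{unlimited, 10, 20\}, per-node feature
#' rule \{sqrt, 0.3\}, minimum leaf size \{1, 5\}. The grid contents are a
#' package choice; pass a reduced grid for quick runs.
#'
#' @return data.frame of grid points.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(100L, 300L, 500L),
              max_depth = c(0L, 10L, 20L),
              max_features = c("sqrt", "0.3"),
              min_node = c(1L, 5L),
              stringsAsFactors = FALSE)
}

.parse_max_features <- function(x) {
  if (identical(x, "sqrt")) "sqrt" else as.numeric(x)
}

.f1_positive <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp); rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}

.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid-search and fit the residue-pair classifier
#'
#' Stratified 75:25 split of the (down-sampled) table; each grid point is
#' scored by cross-validated positive-class F1 on the 75% part; the best
#' point is refit on the 75% part and evaluated once on the held-out 25%.
#' All preprocessing state needed to reproduce inference (kernel spec,
#' secondary-structure ranks, scaling mode, sampling ratio, seed) is stored
#' on the returned model.
#'
#' @param table training table (typically after [downsample_majority()]).
#' @param grid hyperparameter grid (default [default_rf_grid()]).
#' @param seed RNG seed driving the split, folds and forests.
#' @param train_frac training fraction (default 0.75).
#' @param cv_folds folds for grid scoring (default 3).
#' @param preprocess list of preprocessing state to persist: `kernel`
#'   (spec list), `ssp_ranks`, `scaling`, `sampling_ratio`.
#' @return A `trained_model`: the fitted `rf_model` plus `best`,
#'   `cv_results`, `heldout` ([evaluate_predictions()] report on the 25%
#'   split), `features`, `preprocess`, `complex_ids`, `seed`.
#' @export
grid_search_fit <- function(table, grid = default_rf_grid(), seed = 1L,
                            train_frac = 0.75, cv_folds = 3L,
                            preprocess = list()) {
  feats <- .table_features(table)
  if (length(unique(table$label)) < 2L)
    stop_ppiface("training table has a single class")
  x <- as.matrix(table[, feats, drop = FALSE])
  y <- as.integer(table$label)

  res <- with_seed(seed, {
    n <- length(y)
    train_idx <- unlist(lapply(split(seq_len(n), y), function(idx)
      sample(idx, round(train_frac * length(idx)))))
    test_idx <- setdiff(seq_len(n), train_idx)
    ytr <- y[train_idx]
    fold <- .stratified_folds(ytr, cv_folds)
    scores <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      f1s <- numeric(cv_folds)
      for (k in seq_len(cv_folds)) {
        tr <- train_idx[fold != k]; va <- train_idx[fold == k]
        if (length(unique(y[tr])) < 2L) { f1s[k] <- 0; next }
        m <- rf_fit(x[tr, , drop = FALSE], y[tr],
                    num_trees = grid$num_trees[g],
                    max_features = .parse_max_features(grid$max_features[g]),
                    max_depth = grid$max_depth[g],
                    min_node = grid$min_node[g])
        pr <- rf_predict(m, x[va, , drop = FALSE])
        f1s[k] <- .f1_positive(y[va], as.integer(pr > 0.5))
      }
      scores[g] <- mean(f1s)
    }
    best <- which.max(scores)
    final <- rf_fit(x[train_idx, , drop = FALSE], ytr,
                    num_trees = grid$num_trees[best],
                    max_features = .parse_max_features(grid$max_features[best]),
                    max_depth = grid$max_depth[best],
                    min_node = grid$min_node[best])
    prob_te <- rf_predict(final, x[test_idx, , drop = FALSE])
    list(final = final, best = best, scores = scores,
         truth_te = y[test_idx], prob_te = prob_te)
  })

  heldout <- evaluate_vectors(res$truth_te, as.integer(res$prob_te > 0.5),
                              prob = res$prob_te)
  pp <- list(kernel = preprocess$kernel %||% NULL,
             ssp_ranks = preprocess$ssp_ranks %||% default_ssp_ranks(),
             scaling = preprocess$scaling %||% "per_matrix_per_complex",
             sampling_ratio = preprocess$sampling_ratio %||% 5)
  structure(list(rf = res$final,
                 best = cbind(grid[res$best, , drop = FALSE],
                              cv_f1 = res$scores[res$best]),
                 cv_results = cbind(grid, cv_f1 = res$scores),
                 heldout = heldout,
                 features = feats,
                 preprocess = pp,
                 complex_ids = unique(table$complex_id),
                 seed = seed),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model>\n  features:", length(x$features),
      "\n  best grid point:\n")
  print(x$best)
  cat(sprintf("  held-out F1 (positive class): %.3f\n",
              x$heldout$f1_by_class[["1"]]))
  invisible(x)
}

#' Predict a probability matrix for a complex
#'
#' @param model a `trained_model`.
#' @param stack `feature_stack` with the model's features.
#' @param check_kernel if `TRUE` (default), error when the stack's kernel
#'   spec differs from the one stored in the model.
#' @return List with `prob` (M x N probabilities) and `binary`
#'   (`prob > 0.5`).
#' @export
predict_matrix <- function(model, stack, check_kernel = TRUE) {
  stopifnot(inherits(model, "trained_model"), inherits(stack, "feature_stack"))
  miss <- setdiff(model$features, names(stack))
  if (length(miss))
    stop_ppiface("stack missing model feature(s): %s",
                 paste(miss, collapse = ", "))
  if (check_kernel && !is.null(model$preprocess$kernel)) {
    ks <- attr(stack, "kernel")
    if (!is.null(ks) && !identical(unlist(ks[c("size", "decay", "normalized")]),
                                   unlist(model$preprocess$kernel[
                                     c("size", "decay", "normalized")])))
      stop_ppiface("feature stack kernel spec differs from the model's (%s vs %s)",
                   jsonlite::toJSON(ks, auto_unbox = TRUE),
                   jsonlite::toJSON(model$preprocess$kernel, auto_unbox = TRUE))
  }
  M <- attr(stack, "M"); N <- attr(stack, "N")
  x <- vapply(model$features, function(f) as.vector(stack[[f]]),
              numeric(M * N))
  prob <- matrix(rf_predict(model$rf, x), M, N)
  list(prob = prob, binary = (prob > 0.5) * 1L)
}

.rank_auc <- function(truth, prob) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate binary predictions against labels (vector form)
#'
#' @param truth,pred 0/1 vectors.
#' @param prob optional probabilities for AUC.
#' @return An `eval_report`: confusion counts (TN, FP, FN, TP), accuracy,
#'   AUC, per-class/macro/weighted precision, recall and F1, specificity
#'   and Matthews correlation.
#' @export
evaluate_vectors <- function(truth, pred, prob = NULL) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  if (length(truth) != length(pred)) stop_ppiface("length mismatch")
  if (length(truth) == 0L) stop_ppiface("empty evaluation set")
  tp <- sum(truth == 1 & pred == 1); tn <- sum(truth == 0 & pred == 0)
  fp <- sum(truth == 0 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  n <- length(truth)
  div <- function(a, b) if (b == 0) 0 else a / b
  prec <- c("0" = div(tn, tn + fn), "1" = div(tp, tp + fp))
  rec  <- c("0" = div(tn, tn + fp), "1" = div(tp, tp + fn))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  support <- c("0" = tn + fp, "1" = tp + fn)
  wts <- support / n
  mcc_den <- sqrt(as.numeric(tp + fp)) * sqrt(as.numeric(tp + fn)) *
             sqrt(as.numeric(tn + fp)) * sqrt(as.numeric(tn + fn))
  mcc <- if (mcc_den == 0) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / mcc_den
  structure(list(
    confusion = c(TN = tn, FP = fp, FN = fn, TP = tp),
    accuracy = (tp + tn) / n,
    auc = if (is.null(prob)) NA_real_ else .rank_auc(truth, prob),
    precision_by_class = prec, recall_by_class = rec, f1_by_class = f1,
    precision_macro = mean(prec), recall_macro = mean(rec),
    f1_macro = mean(f1),
    precision_weighted = sum(wts * prec),
    recall_weighted = sum(wts * rec),
    f1_weighted = sum(wts * f1),
    specificity = rec[["0"]],
    mcc = mcc,
    n = n), class = "eval_report")
}

#' Evaluate a prediction matrix against a label set
#'
#' @param pred M x N binary matrix (or probability matrix, thresholded at
#'   0.5 and also used for AUC).
#' @param labels a `pair_label_set`.
#' @param prob optional probability matrix when `pred` is already binary.
#' @return An `eval_report`; see [evaluate_vectors()].
#' @export
evaluate_predictions <- function(pred, labels, prob = NULL) {
  stopifnot(inherits(labels, "pair_label_set"))
  if (!identical(dim(pred), c(labels$M, labels$N)))
    stop_ppiface("prediction matrix is %dx%d, labels %dx%d",
                 nrow(pred), ncol(pred), labels$M, labels$N)
  truth <- as.vector(label_matrix(labels))
  if (is.null(prob) && any(pred > 0 & pred < 1)) {
    prob <- pred
    pred <- (pred > 0.5) * 1L
  }
  evaluate_vectors(truth, as.vector(pred),
                   prob = if (is.null(prob)) NULL else as.vector(prob))
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  cat("  confusion:", paste(names(x$confusion), x$confusion,
                            collapse = "  "), "\n")
  cat(sprintf("  accuracy %.3f  AUC %s  MCC %.3f  specificity %.3f\n",
              x$accuracy,
              if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc),
              x$mcc, x$specificity))
  cat(sprintf("  F1 macro %.3f / weighted %.3f\n", x$f1_macro,
              x$f1_weighted))
  invisible(x)
}

#' Leave-one-complex-out cross-validation
#'
#' For each complex: assemble the training table from all other complexes
#' (down-sampled per complex), grid-search and fit, then evaluate on the
#' held-out complex's full, un-sampled pair grid.
#'
#' @param complexes named list; each element a list with `stack` (18
#'   features) and `labels` (`pair_label_set`).
#' @param ratio negatives per positive for the training tables.
#' @param grid hyperparameter grid.
#' @param seed base RNG seed; per-fold seeds are derived from it.
#' @return Named list of per-complex `eval_report`s with attribute
#'   `models` (the per-fold `trained_model`s).
#' @export
leave_one_out <- function(complexes, ratio = 5, grid = default_rf_grid(),
                          seed = 1L) {
  ids <- names(complexes)
  if (is.null(ids) || anyDuplicated(ids))
    stop_ppiface("complexes must be a uniquely named list")
  if (length(complexes) < 2L) stop_ppiface("need at least 2 complexes")
  reports <- list(); models <- list()
  for (k in seq_along(ids)) {
    train_ids <- ids[-k]
    tables <- lapply(seq_along(train_ids), function(t) {
      cx <- complexes[[train_ids[t]]]
      downsample_majority(
        build_training_table(cx$stack, cx$labels, complex_id = train_ids[t]),
        ratio = ratio, seed = derive_seed(seed, k * 101L + t))
    })
    feats <- .table_features(tables[[1L]])
    table <- do.call(rbind, tables)
    attr(table, "features") <- feats
    model <- grid_search_fit(table, grid = grid,
                             seed = derive_seed(seed, k),
                             preprocess = list(sampling_ratio = ratio))
    held <- complexes[[ids[k]]]
    pm <- predict_matrix(model, held$stack, check_kernel = FALSE)
    reports[[ids[k]]] <- evaluate_predictions(pm$binary, held$labels,
                                              prob = pm$prob)
    models[[ids[k]]] <- model
  }
  attr(reports, "models") <- models
  reports
}

#' Ranked feature importance
#'
#' Mean decrease in gini impurity, normalized to sum 1, sorted descending.
#'
#' @param model a `trained_model` (or `rf_model`).
#' @return data.frame with columns `feature`, `importance`.
#' @export
feature_importance <- function(model) {
  rf <- if (inherits(model, "trained_model")) model$rf else model
  if (!inherits(rf, "rf_model")) stop_ppiface("not a fitted model")
  imp <- rf$importance
  names(imp) <- rf$feature_names %||% paste0("f", seq_along(imp))
  imp <- sort(imp, decreasing = TRUE)
  data.frame(feature = names(imp), importance = unname(imp))
}
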