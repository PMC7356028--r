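test_that("downsample_majority keeps positives and samples negatives", {
  tab <- make_separable_table(n_pos = 100, ratio = 100)  # 10,000 negatives
  out <- downsample_majority(tab, ratio = 5, seed = 2)
  expect_equal(nrow(out), 600L)
  expect_equal(sum(out$label), 100L)

  few <- make_separable_table(n_pos = 100, ratio = 3)    # only 300 negatives
  expect_equal(nrow(downsample_majority(few, ratio = 5, seed = 1)), 400L)

  expect_identical(downsample_majority(tab, 5, seed = 7),
                   downsample_majority(tab, 5, seed = 7))
  allneg <- tab[tab$label == 0, ]
  expect_error(downsample_majority(allneg, 5, seed = 1), "positive")
})

test_that("grid search separates a planted-separation fixture", {
  tab <- make_separable_table(seed = 1)
  model <- grid_search_fit(tab, grid = small_grid(), seed = 11)
  expect_s3_class(model, "trained_model")
  expect_gte(model$heldout$f1_by_class[["1"]], 0.95)
  expect_identical(model$features, feature_names(TRUE))
  expect_equal(model$preprocess$sampling_ratio, 5)
  expect_error(grid_search_fit(tab[tab$label == 0, ], grid = small_grid()),
               "single class")
})

test_that("training is reproducible under a fixed seed", {
  tab <- make_separable_table(n_pos = 40, seed = 3)
  m1 <- grid_search_fit(tab, grid = small_grid(), seed = 5)
  m2 <- grid_search_fit(tab, grid = small_grid(), seed = 5)
  expect_identical(m1$cv_results, m2$cv_results)
  x <- as.matrix(tab[, feature_names(TRUE)])
  expect_identical(rf_predict(m1$rf, x), rf_predict(m2$rf, x))
})

test_that("predict_matrix is consistent with its probabilities", {
  case <- make_synthetic_case(51)
  tab <- downsample_majority(build_training_table(case$stack, case$labels),
                             ratio = 5, seed = 1)
  model <- grid_search_fit(tab, grid = small_grid(), seed = 9,
                           preprocess = list(kernel = attr(case$stack, "kernel")))
  pm <- predict_matrix(model, case$stack)
  expect_identical(dim(pm$prob), dim(pm$binary))
  expect_true(all(pm$prob >= 0 & pm$prob <= 1))
  expect_true(all(pm$binary %in% c(0L, 1L)))
  expect_identical(pm$binary, (pm$prob > 0.5) * 1L)

  # constant feature rows give a constant probability matrix
  const <- lapply(case$stack, function(m) matrix(m[1, 1], nrow(m), ncol(m)))
  const <- structure(const, M = attr(case$stack, "M"),
                     N = attr(case$stack, "N"),
                     kernel = attr(case$stack, "kernel"),
                     class = "feature_stack")
  pc <- predict_matrix(model, const)
  expect_equal(length(unique(as.vector(pc$prob))), 1L)

  broken <- case$stack[-1]
  attr(broken, "M") <- attr(case$stack, "M")
  attr(broken, "N") <- attr(case$stack, "N")
  class(broken) <- "feature_stack"
  expect_error(predict_matrix(model, broken), "CMI")

  # kernel metadata guard
  other <- case$stack
  attr(other, "kernel") <- list(size = 7L, decay = 0.25, normalized = TRUE)
  expect_error(predict_matrix(model, other), "kernel")
})

test_that("evaluate reports the closed-form confusion arithmetic", {
  truth <- c(rep(1, 10), rep(0, 90))
  perfect <- evaluate_vectors(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1_macro, 1)

  allneg <- evaluate_vectors(truth, rep(0, 100))
  expect_equal(allneg$accuracy, 0.9)
  expect_equal(unname(allneg$recall_by_class[["1"]]), 0)
  expect_equal(allneg$mcc, 0)
  expect_equal(allneg$specificity, 1)
  expect_equal(unname(allneg$confusion),
               c(90L, 0L, 10L, 0L))               # TN FP FN TP

  # internal consistency: metrics recomputed from the confusion cells
  set.seed(8)
  pred <- rbinom(100, 1, 0.3)
  rep_ <- evaluate_vectors(truth, pred)
  cm <- rep_$confusion
  expect_equal(sum(cm), rep_$n)
  expect_equal(rep_$accuracy, (cm[["TP"]] + cm[["TN"]]) / sum(cm))
  prec1 <- cm[["TP"]] / (cm[["TP"]] + cm[["FP"]])
  expect_equal(unname(rep_$precision_by_class[["1"]]), prec1)
  expect_error(evaluate_vectors(integer(0), integer(0)), "empty")
})

test_that("AUC equals the rank-sum statistic", {
  truth <- c(0, 0, 1, 1)
  expect_equal(evaluate_vectors(truth, truth, prob = c(0.1, 0.2, 0.8, 0.9))$auc, 1)
  expect_equal(evaluate_vectors(truth, truth, prob = c(0.9, 0.8, 0.2, 0.1))$auc, 0)
  expect_equal(evaluate_vectors(truth, truth, prob = c(0.5, 0.5, 0.5, 0.5))$auc, 0.5)
})

test_that("leave_one_out keeps folds leak-free", {
  complexes <- list(c1 = NULL, c2 = NULL, c3 = NULL)
  for (k in 1:3) {
    case <- make_synthetic_case(60 + k)
    complexes[[k]] <- list(stack = case$stack, labels = case$labels)
  }
  reports <- leave_one_out(complexes, ratio = 5,
                           grid = small_grid()[1, , drop = FALSE], seed = 2)
  expect_length(reports, 3L)
  models <- attr(reports, "models")
  for (id in names(complexes)) {
    expect_false(id %in% models[[id]]$complex_ids)   # held-out never trained on
    expect_setequal(models[[id]]$complex_ids, setdiff(names(complexes), id))
    expect_equal(reports[[id]]$n,
                 attr(complexes[[id]]$stack, "M") *
                   attr(complexes[[id]]$stack, "N"))
  }
  expect_error(leave_one_out(complexes[1], grid = small_grid()), "at least 2")
  unnamed <- unname(complexes)
  expect_error(leave_one_out(unnamed, grid = small_grid()), "named")
})

test_that("feature importance is a ranked simplex over the 18 features", {
  tab <- make_separable_table(seed = 4)
  model <- grid_search_fit(tab, grid = small_grid()[1, , drop = FALSE],
                           seed = 3)
  fi <- feature_importance(model)
  expect_equal(nrow(fi), 18L)
  expect_equal(sum(fi$importance), 1, tolerance = 1e-9)
  expect_true(all(diff(fi$importance) <= 0))
  expect_true(all(fi$importance >= 0))
  # the fixture's signal features must dominate the ranking
  expect_true(all(feature_names(TRUE)[1:2] %in% fi$feature[1:8]))
  expect_error(feature_importance(list()), "fitted")
})

test_that("a CMI-only signal puts CMI/ECMI near the top", {
  hits <- 0L
  for (s in 1:5) {
    case <- make_synthetic_case(70 + s, M = 16, N = 14, n_interface = 4,
                                n_sequences = 200)
    # silence every feature except CMI and its environment derivative
    stack <- case$stack
    set.seed(s)
    for (f in setdiff(names(stack), c("CMI", "ECMI")))
      stack[[f]] <- matrix(runif(length(stack[[f]])), nrow(stack[[f]]))
    tab <- downsample_majority(build_training_table(stack, case$labels),
                               ratio = 5, seed = s)
    model <- grid_search_fit(tab, grid = small_grid()[1, , drop = FALSE],
                             seed = s)
    fi <- feature_importance(model)
    if (any(c("CMI", "ECMI") %in% fi$feature[1:3])) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
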