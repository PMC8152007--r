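# Confusion matrices, Eq.-style metrics, and leave-one-out cross-validation.

test_that("recall and error-rate arithmetic matches the worked counts", {
  # 452 correct chair predictions from 499 observations -> recall 91%
  m <- metrics_from_counts(tp = 452, fp = 10, tn = 0, fn = 499 - 452)
  expect_equal(m$recall, 452 / 499, tolerance = 1e-12)
  expect_identical(round(100 * m$recall), 91)
  # 130 of 555 stair observations predicted walking -> 23% of the time
  expect_identical(round(100 * 130 / 555), 23)
  # perfect classifier
  p <- metrics_from_counts(1, 0, 1, 0)
  expect_identical(c(p$accuracy, p$precision, p$recall), c(1, 1, 1))
})

test_that("undefined precision/recall are flagged, never zeroed", {
  m <- metrics_from_counts(tp = 0, fp = 0, tn = 5, fn = 3)
  expect_true(is.na(m$precision))
  expect_identical(m$undefined, "precision")
  m2 <- metrics_from_counts(tp = 0, fp = 2, tn = 5, fn = 0)
  expect_true(is.na(m2$recall))
  expect_identical(m2$undefined, "recall")
  expect_error(metrics_from_counts(-1, 0, 0, 1))
})

test_that("confusion matrices count, permute and reject correctly", {
  true <- c("a", "a", "b", "b", "b", "c", "c", "c", "c", "c")
  pred <- c("a", "b", "b", "b", "c", "c", "c", "c", "a", "c")
  cm <- confusion(true, pred, c("a", "b", "c"))
  expect_identical(sum(diag(cm)), 7L)
  expect_identical(sum(cm), 10L)
  # permuted class order permutes the matrix
  cm2 <- confusion(true, pred, c("c", "a", "b"))
  expect_identical(unclass(cm2)[c("a", "b", "c"), c("a", "b", "c")],
                   unclass(cm)[c("a", "b", "c"), c("a", "b", "c")])
  expect_identical(sum(diag(confusion(true, true, c("a", "b", "c")))), 10L)
  expect_error(confusion(c("a", "z"), c("a", "a"), c("a", "b")), "outside")
  expect_error(confusion("a", c("a", "b")), "equal length")
})

test_that("metrics agree with brute-force recounting on random sequences", {
  set.seed(17)
  classes <- c("x", "y", "z")
  for (i in 1:25) {
    n <- sample(5:60, 1)
    true <- sample(classes, n, TRUE)
    pred <- sample(classes, n, TRUE)
    cm <- confusion(true, pred, classes)
    met <- confusion_metrics(cm)
    expect_equal(met$accuracy, mean(true == pred), tolerance = 1e-12)
    for (cl in classes) {
      tp <- sum(true == cl & pred == cl)
      fp <- sum(true != cl & pred == cl)
      fn <- sum(true == cl & pred != cl)
      tn <- n - tp - fp - fn
      expect_identical(met$per_class[[cl]]$tp, tp)
      ref <- metrics_from_counts(tp, fp, tn, fn)
      expect_equal(met$per_class[[cl]]$accuracy, ref$accuracy)
      expect_equal(met$per_class[[cl]]$precision, ref$precision)
      expect_equal(met$per_class[[cl]]$recall, ref$recall)
    }
  }
})

fast_specs <- function(epochs = 3) {
  har_node_specs(list(`1` = window_config(1, 200, 50),
                      `2` = window_config(2, 100, 20),
                      `3` = window_config(3, 40, 20)),
                 train_params(max_epochs = epochs, patience = 2,
                              filters = c(8L, 16L), dense_units = 16L))
}

test_that("loocv makes one fold per participant and pools by summation", {
  ds <- tiny_cohort(n = 2, battery = c(chair = 2, stairs_up = 1,
                                       stairs_down = 1, walking = 1))
  rep <- loocv(ds, fast_specs(), seed = 21)
  expect_length(rep$folds, 2)
  expect_setequal(names(rep$folds), ds$participants)
  for (id in names(rep$pooled)) {
    fold_sum <- Reduce(`+`, lapply(
      Filter(function(f) !is.null(f[[id]]), rep$folds),
      function(f) unclass(f[[id]])))
    expect_identical(as.vector(unclass(rep$pooled[[id]])),
                     as.vector(fold_sum))
    expect_identical(sum(rep$pooled[[id]]),
                     sum(vapply(rep$folds, function(f)
                       if (is.null(f[[id]])) 0L else sum(f[[id]]), 0L)))
  }
  expect_error(loocv(structure(list(trials = ds$trials, participants = "P01"),
                               class = "har_dataset"), fast_specs()),
               ">= 2 participants")
})

test_that("loocv is deterministic under a fixed master seed", {
  ds <- tiny_cohort(n = 2, battery = c(chair = 1, stairs_up = 1,
                                       stairs_down = 1, walking = 1))
  a <- loocv(ds, fast_specs(epochs = 2), seed = 33)
  b <- loocv(ds, fast_specs(epochs = 2), seed = 33)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
})

test_that("normalization and training depend on the training fold only", {
  ds <- tiny_cohort(n = 3, battery = c(chair = 1, stairs_up = 1,
                                       stairs_down = 1, walking = 1))
  train_a <- Filter(function(tr) tr$participant_id != "P01", ds$trials)
  train_b <- Filter(function(tr) tr$participant_id != "P02", ds$trials)
  ta1 <- train_tree(train_a, fast_specs(epochs = 2), seed = 9)
  ta2 <- train_tree(train_a, fast_specs(epochs = 2), seed = 9)
  tb <- train_tree(train_b, fast_specs(epochs = 2), seed = 9)
  expect_identical(ta1$stats, ta2$stats)
  expect_identical(ta1$nodes$level1$net, ta2$nodes$level1$net)
  expect_false(identical(ta1$stats$level1, tb$stats$level1))
})

test_that("higher class separation never hurts level-1 accuracy", {
  accs <- vapply(c(0.4, 1.2, 2.5), function(sep) {
    ds <- tiny_cohort(n = 2, battery = c(chair = 1, stairs_up = 1,
                                         stairs_down = 1, walking = 1),
                      seed = 55, separation = sep)
    spec1 <- fast_specs(epochs = 3)$level1
    acc <- vapply(ds$participants, function(p) {
      tr <- Filter(function(t) t$participant_id != p, ds$trials)
      te <- Filter(function(t) t$participant_id == p, ds$trials)
      ws <- node_windows(tr, spec1)
      bal <- ws_subset(ws, balance_by_class(ws$label, seed = 3))
      st <- fit_normalization(bal)
      spec1$params$seed <- 3
      tn <- train_node(spec1, encode_windows(bal, st))
      wte <- node_windows(te, spec1)
      probs <- predict_node(tn, encode_windows(wte, st))
      mean(spec1$classes[apply(probs, 1, which.max)] == wte$label)
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))
})

test_that("predicted-routing evaluation produces per-node confusions", {
  ds <- tiny_cohort(n = 2, battery = c(chair = 1, stairs_up = 1,
                                       stairs_down = 1, walking = 1))
  rep <- loocv(ds, fast_specs(epochs = 2), seed = 12, routing = "predicted")
  expect_true("level1" %in% names(rep$pooled))
  expect_gt(sum(rep$pooled$level1), 0)
  expect_true(all(rep$node_summary$pooled_accuracy >= 0 &
                  rep$node_summary$pooled_accuracy <= 1))
})
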