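# Leave-one-out cross-validation over participants and the standard
# confusion-matrix metrics:
#   accuracy  = (TP + TN) / (TP + FP + TN + FN)
#   precision = TP / (TP + FP)
#   recall    = TP / (TP + FN)
# Multiclass nodes are reduced one-vs-rest per class; undefined ratios are
# reported as NA with a flag rather than silently zeroed.

#' Confusion matrix
#'
#' Cross-tabulates true against predicted labels: cell (i, j) counts
#' windows with true class i predicted as class j, so the diagonal sum over
#' the grand total is the multiclass accuracy.
#'
#' @param true,predicted equal-length label vectors.
#' @param classes class order for rows/columns; both label vectors must lie
#'   within it.
#' @return Integer matrix (rows = true, columns = predicted) of class
#'   `"confusion_matrix"`.
#' @export
confusion <- function(true, predicted, classes = sort(unique(c(true, predicted)))) {
  if (length(true) != length(predicted))
    stopf("true and predicted must have equal length")
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad))
    stopf("label(s) [%s] outside class order", paste(bad, collapse = ", "))
  m <- table(factor(true, levels = classes),
             factor(predicted, levels = classes))
  structure(unclass(m), dimnames = list(true = classes, predicted = classes),
            class = c("confusion_matrix", "matrix"))
}

#' Accuracy, precision and recall from binary counts
#'
#' Exact evaluation of the three standard formulas from true/false
#' positive/negative counts. A precision with `TP + FP = 0` or a recall
#' with `TP + FN = 0` is undefined: it is returned as `NA` and flagged in
#' `$undefined`, never silently set to 0.
#'
#' @param tp,fp,tn,fn non-negative counts (at least one positive).
#' @return List of class `"har_metrics"` with the four counts, `accuracy`,
#'   `precision`, `recall` and an `undefined` character vector.
#' @examples
#' m <- metrics_from_counts(tp = 452, fp = 0, tn = 0, fn = 47)
#' round(100 * m$recall)   # 91
#' @export
metrics_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  undef <- character(0)
  precision <- if (tp + fp == 0) { undef <- c(undef, "precision"); NA_real_ }
               else tp / (tp + fp)
  recall <- if (tp + fn == 0) { undef <- c(undef, "recall"); NA_real_ }
            else tp / (tp + fn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 accuracy = (tp + tn) / (tp + fp + tn + fn),
                 precision = precision, recall = recall,
                 undefined = undef), class = "har_metrics")
}

#' Per-class and overall metrics from a confusion matrix
#'
#' Reduces a (possibly multiclass) confusion matrix one-vs-rest: for each
#' class, TP is its diagonal cell, FP its column remainder, FN its row
#' remainder and TN everything else. Also reports the multiclass accuracy
#' (diagonal sum over grand total) and macro averages of the defined
#' per-class precisions/recalls.
#'
#' @param cm a [confusion()] matrix.
#' @return List with `accuracy`, `per_class` (list of [metrics_from_counts()]
#'   results), `macro_precision`, `macro_recall` and `n` (total count).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  per_class <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[-i, i]); fn <- sum(cm[i, -i])
    metrics_from_counts(tp, fp, total - tp - fp - fn, fn)
  })
  names(per_class) <- rownames(cm)
  prec <- vapply(per_class, `[[`, numeric(1), "precision")
  rec <- vapply(per_class, `[[`, numeric(1), "recall")
  list(accuracy = sum(diag(cm)) / total,
       per_class = per_class,
       macro_precision = mean(prec, na.rm = TRUE),
       macro_recall = mean(rec, na.rm = TRUE),
       n = total)
}

# Truth-routed evaluation of one trained node on held-out trials: the
# node sees exactly the windows its ground-truth scope defines.
.eval_node_truth <- function(trained, stats, trials) {
  spec <- trained$spec
  ws <- tryCatch(node_windows(trials, spec), error = function(e) NULL)
  if (is.null(ws)) return(NULL)
  ws <- ws_subset(ws, which(!is.na(ws$label)))
  if (length(ws$label) == 0) return(NULL)
  enc <- encode_windows(ws, stats)
  probs <- predict_node(trained, enc)
  pred <- spec$classes[apply(probs, 1, which.max)]
  confusion(ws$label, pred, spec$classes)
}

# Predicted-routing evaluation: classify each trial through the tree and
# compare each decision against the majority true label of its span.
.eval_fold_predicted <- function(tree, trials) {
  cms <- list()
  for (trial in trials) {
    dec <- classify_windows(tree, trial)
    if (nrow(dec) == 0) next
    fs <- trial$sample_rate_hz
    for (id in unique(dec$node_id)) {
      trained <- tree$nodes[[id]]
      d <- dec[dec$node_id == id, ]
      track <- switch(trained$spec$level, trial$level1, trial$level2,
                      trial$level3)
      truth <- vapply(seq_len(nrow(d)), function(i) {
        a <- as.integer(round((d$start_s[i] - trial$start_s) * fs)) + 1L
        b <- a + trained$spec$window_config$window_samples - 1L
        .window_label(track[a:min(b, length(track))])
      }, character(1))
      ok <- !is.na(truth) & truth %in% trained$spec$classes
      if (!any(ok)) next
      cm <- confusion(truth[ok], d$predicted[ok], trained$spec$classes)
      cms[[id]] <- if (is.null(cms[[id]])) cm else {
        s <- cms[[id]] + cm
        structure(s, dimnames = dimnames(cm),
                  class = c("confusion_matrix", "matrix"))
      }
    }
  }
  cms
}

#' Leave-one-out cross-validation of the full system
#'
#' One fold per participant: the six nodes are trained on all other
#' participants (balancing, normalization and network fitting all see the
#' training fold only) and evaluated on the held-out participant's windows.
#' By default each node is evaluated on its ground-truth-routed windows, so
#' per-node accuracies are independent of upstream mistakes; with
#' `routing = "predicted"` the held-out trials are instead pushed through
#' the full decision tree and every emitted decision is scored against the
#' majority true label of its span.
#'
#' @param dataset a `har_dataset` with >= 2 participants.
#' @param specs six [node_spec()]s (see [har_node_specs()]).
#' @param seed master seed; every random stage (balancing, validation
#'   splits, initialization, dropout) derives from it, so the report is a
#'   deterministic function of (dataset, specs, seed).
#' @param routing `"truth"` (default) or `"predicted"`.
#' @return Object of class `"loocv_report"`: `folds` (per participant: per
#'   node confusion matrix), `pooled` (per node: summed confusion),
#'   `node_summary` data frame with mean-across-folds accuracy (the
#'   headline), pooled accuracy, macro precision/recall, and `settings`.
#' @export
loocv <- function(dataset, specs = har_node_specs(), seed = 1L,
                  routing = c("truth", "predicted")) {
  routing <- match.arg(routing)
  stopifnot(inherits(dataset, "har_dataset"))
  parts <- dataset$participants
  if (length(parts) < 2) stopf("leave-one-out needs >= 2 participants")

  folds <- list()
  for (p in parts) {
    train_trials <- Filter(function(tr) tr$participant_id != p, dataset$trials)
    test_trials <- Filter(function(tr) tr$participant_id == p, dataset$trials)
    tree <- train_tree(train_trials, specs, seed = derive_seed(seed, "fold", p))
    folds[[p]] <- if (routing == "truth") {
      cms <- lapply(NODE_IDS, function(id) {
        if (is.null(tree$nodes[[id]])) return(NULL)
        .eval_node_truth(tree$nodes[[id]], tree$stats[[id]], test_trials)
      })
      stats::setNames(cms, NODE_IDS)
    } else {
      .eval_fold_predicted(tree, test_trials)
    }
  }

  pooled <- list()
  for (id in NODE_IDS) {
    mats <- Filter(Negate(is.null), lapply(folds, `[[`, id))
    if (length(mats) == 0) next
    s <- Reduce(`+`, lapply(mats, unclass))
    pooled[[id]] <- structure(s, dimnames = dimnames(mats[[1]]),
                              class = c("confusion_matrix", "matrix"))
  }

  node_summary <- do.call(rbind, lapply(names(pooled), function(id) {
    fold_acc <- vapply(folds, function(f) {
      if (is.null(f[[id]])) return(NA_real_)
      sum(diag(f[[id]])) / sum(f[[id]])
    }, numeric(1))
    cm <- confusion_metrics(pooled[[id]])
    data.frame(node = id,
               mean_fold_accuracy = mean(fold_acc, na.rm = TRUE),
               pooled_accuracy = cm$accuracy,
               macro_precision = cm$macro_precision,
               macro_recall = cm$macro_recall,
               n_windows = cm$n)
  }))
  rownames(node_summary) <- NULL

  structure(list(folds = folds, pooled = pooled, node_summary = node_summary,
                 settings = list(seed = seed, routing = routing,
                                 n_participants = length(parts))),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %d folds, routing = %s\n",
              x$settings$n_participants, x$settings$routing))
  print(x$node_summary, digits = 3)
  invisible(x)
}
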