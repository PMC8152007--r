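# Decision-tree dispatch: a level-1 activity classifier routes window
# spans to direction classifiers (chair, stairs) and on to stance/swing
# phase classifiers. Walking has no direction split and routes straight to
# its phase node. Each node classifies its own window grid within the span
# handed to it.

.routing <- function() {
  list(level1 = c(chair = "chair_dir", stairs = "stairs_dir",
                  walking = "walking_phase"),
       stairs_dir = c(stairs_ascending = "stairs_up_phase",
                      stairs_descending = "stairs_down_phase"),
       chair_dir = character(0))   # chair directions are leaves
}

#' Train the full decision tree on a set of trials
#'
#' For each of the six nodes: collect the node's labeled windows, balance
#' classes by random downsampling, fit the 0-255 normalization constants on
#' the balanced training windows, encode, and train the node's network.
#' All randomness fans out from `seed` via [derive_seed()].
#'
#' @param trials list of `har_trial`s (the training fold).
#' @param specs six [node_spec()]s, as from [har_node_specs()].
#' @param seed master seed for balancing and training.
#' @return Object of class `"har_tree"`: trained `nodes`, per-node
#'   normalization `stats`, the `specs` and the routing table.
#' @export
train_tree <- function(trials, specs = har_node_specs(), seed = 1L) {
  stopifnot(setequal(names(specs), NODE_IDS))
  nodes <- list(); stats <- list()
  for (id in NODE_IDS) {
    spec <- specs[[id]]
    ws <- node_windows(trials, spec)
    missing <- setdiff(spec$classes, unique(ws$label))
    if (length(missing)) {
      warnf("node %s: class(es) [%s] absent from training windows; node skipped",
            id, paste(missing, collapse = ", "))
      next
    }
    idx <- balance_by_class(ws$label, seed = derive_seed(seed, "balance", id))
    bal <- ws_subset(ws, idx)
    st <- fit_normalization(bal)
    enc <- encode_windows(bal, st)
    spec$params$seed <- derive_seed(seed, "train", id)
    nodes[[id]] <- train_node(spec, enc)
    stats[[id]] <- st
  }
  structure(list(nodes = nodes, stats = stats, specs = specs,
                 routing = .routing()), class = "har_tree")
}

.crop_trial <- function(trial, t0, t1) {
  abs_t <- trial$start_s + trial$time_s
  keep <- abs_t >= t0 - 1e-9 & abs_t < t1 - 1e-9
  trial$channels <- trial$channels[, keep, drop = FALSE]
  for (f in c("level1", "level2", "level3")) trial[[f]] <- trial[[f]][keep]
  trial$time_s <- abs_t[keep] - t0
  trial$start_s <- t0
  trial$end_s <- t1
  trial
}

.node_decisions <- function(tree, trial, node_id, path) {
  trained <- tree$nodes[[node_id]]
  if (is.null(trained))
    stopf("missing child model for node '%s'", node_id)
  cfg <- trained$spec$window_config
  ws <- .segment_raw(trial, cfg, trained$spec$level)
  n <- length(ws$start_s)
  if (n == 0) return(NULL)
  enc <- encode_windows(ws, tree$stats[[node_id]])
  probs <- predict_node(trained, enc)
  pick <- apply(probs, 1, which.max)     # ties -> first class in order
  pred <- trained$spec$classes[pick]
  data.frame(
    participant_id = trial$participant_id, trial_id = trial$trial_id,
    node_id = node_id, level = trained$spec$level,
    start_s = ws$start_s, end_s = ws$start_s + cfg$window_ms / 1000,
    predicted = pred, probability = probs[cbind(seq_len(n), pick)],
    path = paste0(paste(path, collapse = ""), pred),
    stringsAsFactors = FALSE)
}

# spans of consecutive windows sharing one predicted class; each span
# covers [first window start, last window start + window duration)
.spans <- function(dec) {
  r <- rle(dec$predicted)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(predicted = r$values,
             t0 = dec$start_s[starts], t1 = dec$end_s[ends])
}

#' Classify a trial through the decision tree
#'
#' Level-1 windows (200 ms grid by default) are classified first;
#' contiguous runs of one predicted activity form spans, and the routed
#' child node then classifies its own finer window grid inside each span
#' (stair spans pass through the direction node before the phase nodes).
#' No label track is consulted. Ties in a node's probability vector break
#' toward the earlier class in the node's documented class order.
#'
#' @param tree a trained [train_tree()].
#' @param trial a `har_trial`.
#' @return Data frame of window decisions: `participant_id`, `trial_id`,
#'   `node_id`, `level`, `start_s`, `end_s`, `predicted`, `probability`
#'   and the ancestor `path` (e.g. `"stairs/stairs_ascending/stance"`).
#'   Empty (with a warning) when the trial is shorter than the level-1
#'   window.
#' @export
classify_windows <- function(tree, trial) {
  stopifnot(inherits(tree, "har_tree"), inherits(trial, "har_trial"))
  d1 <- .node_decisions(tree, trial, "level1", character(0))
  if (is.null(d1)) {
    warnf("trial %s is shorter than the level-1 window; no decisions",
          trial$trial_id)
    return(data.frame())
  }
  d1$path <- d1$predicted
  out <- list(d1)
  for (i in seq_len(nrow(sp1 <- .spans(d1)))) {
    child <- tree$routing$level1[[sp1$predicted[i]]]
    sub <- .crop_trial(trial, sp1$t0[i], sp1$t1[i])
    d2 <- .node_decisions(tree, sub, child, paste0(sp1$predicted[i], "/"))
    if (is.null(d2)) next
    out[[length(out) + 1L]] <- d2
    if (child == "stairs_dir") {
      for (j in seq_len(nrow(sp2 <- .spans(d2)))) {
        phase_node <- tree$routing$stairs_dir[[sp2$predicted[j]]]
        sub2 <- .crop_trial(trial, sp2$t0[j], sp2$t1[j])
        d3 <- .node_decisions(tree, sub2, phase_node,
                              paste0(sp1$predicted[i], "/", sp2$predicted[j], "/"))
        if (!is.null(d3)) out[[length(out) + 1L]] <- d3
      }
    }
  }
  dec <- do.call(rbind, out)
  rownames(dec) <- NULL
  dec
}

#' Resolve two competing decisions for one window span
#'
#' When one window span receives two candidate classifications (e.g. a
#' boundary window between two phases), the decision with the higher
#' maximum class probability wins; an exact tie goes to the earlier class
#' in the node's documented class order and is logged.
#'
#' @param a,b one-row decision data frames (as emitted by
#'   [classify_windows()]) covering the same span at the same level.
#' @return The winning decision row.
#' @export
resolve_overlap <- function(a, b) {
  if (a$level != b$level || abs(a$start_s - b$start_s) > 1e-9 ||
      abs(a$end_s - b$end_s) > 1e-9)
    stopf("decisions cover different spans; cannot resolve")
  if (a$probability > b$probability) return(a)
  if (b$probability > a$probability) return(b)
  classes <- node_spec(a$node_id)$classes
  winner <- if (match(a$predicted, classes) <= match(b$predicted, classes)) a else b
  message(sprintf("probability tie at %.3f s resolved toward '%s' by class order",
                  a$start_s, winner$predicted))
  winner
}

#' Aggregate window decisions for a trial
#'
#' Counts predicted labels per level and reports the modal label with its
#' support fraction, the per-trial summary used to count window
#' "observations" per class.
#'
#' @param decisions a [classify_windows()] data frame (>= 1 row).
#' @return Named list (one element per level present) with `counts`, the
#'   modal `label` and its `support` fraction.
#' @export
aggregate_trial <- function(decisions) {
  if (is.null(decisions) || nrow(decisions) == 0)
    stopf("no decisions to aggregate")
  out <- list()
  for (lv in sort(unique(decisions$level))) {
    d <- decisions[decisions$level == lv, ]
    counts <- table(d$predicted)
    out[[as.character(lv)]] <- list(
      counts = counts,
      label = names(counts)[which.max(counts)],
      support = max(counts) / sum(counts))
  }
  out
}
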