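# The six classification nodes of the decision tree: one level-1 activity
# classifier (two convolutional layers) and five level-2/3 classifiers
# (three convolutional layers each), trained with Adam on balanced,
# encoded window images with dropout and early stopping.

NODE_IDS <- c("level1", "chair_dir", "stairs_dir",
              "stairs_up_phase", "stairs_down_phase", "walking_phase")

#' Training hyper-parameters for one node
#'
#' @param learning_rate Adam learning rate (default 1e-3; tunable per node).
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience: training halts when validation
#'   loss has not improved for this many consecutive epochs, and the
#'   best-epoch parameters are kept.
#' @param dropout_rate dropout on the dense layer during training.
#' @param batch_size minibatch size.
#' @param val_fraction fraction of training windows held out (stratified by
#'   class) as the early-stopping validation split.
#' @param filters convolutional filter counts per layer.
#' @param dense_units width of the fully connected layer.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return List of class `"train_params"`.
#' @export
train_params <- function(learning_rate = 1e-3, max_epochs = 12L,
                         patience = 3L, dropout_rate = 0.3,
                         batch_size = 64L, val_fraction = 0.1,
                         filters = c(16L, 32L, 64L), dense_units = 64L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1, patience >= 1,
            dropout_rate >= 0, dropout_rate < 1,
            batch_size >= 1, val_fraction > 0, val_fraction < 0.5)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 dropout_rate = dropout_rate,
                 batch_size = as.integer(batch_size),
                 val_fraction = val_fraction,
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 seed = as.integer(seed)), class = "train_params")
}

#' Specification of one classification node
#'
#' @param node_id one of `"level1"`, `"chair_dir"`, `"stairs_dir"`,
#'   `"stairs_up_phase"`, `"stairs_down_phase"`, `"walking_phase"`.
#' @param window_config the node's [window_config()]; defaults to the
#'   node's level with the standard sizes.
#' @param params a [train_params()].
#' @return Object of class `"node_spec"` carrying the node's ordered class
#'   list (the tie-break order), its convolution depth (2 at level 1, 3 at
#'   levels 2 and 3) and its window configuration.
#' @export
node_spec <- function(node_id, window_config = NULL, params = train_params()) {
  if (!node_id %in% NODE_IDS)
    stopf("unknown node_id '%s'", node_id)
  tax <- har_taxonomy()
  classes <- switch(node_id,
    level1 = tax$level1,
    chair_dir = tax$level2_chair,
    stairs_dir = tax$level2_stairs,
    tax$level3)
  level <- switch(node_id, level1 = 1L, chair_dir = 2L, stairs_dir = 2L, 3L)
  structure(list(node_id = node_id, classes = classes,
                 conv_layers = if (node_id == "level1") 2L else 3L,
                 level = level,
                 window_config = window_config %||% window_config(level),
                 params = params), class = "node_spec")
}

#' The six default node specifications
#'
#' One spec per node of the decision tree; together their class sets cover
#' the whole taxonomy (level 1 activities, chair directions, stair
#' directions and the three stance/swing phase contexts).
#'
#' @param window_configs optional named list level -> [window_config()]
#'   (names `"1"`, `"2"`, `"3"`) overriding the per-level defaults.
#' @param params a [train_params()] applied to every node, or a named list
#'   node_id -> [train_params()].
#' @return Named list of six [node_spec()]s.
#' @export
har_node_specs <- function(window_configs = NULL, params = train_params()) {
  wc <- function(level) {
    if (!is.null(window_configs)) window_configs[[as.character(level)]]
    else window_config(level)
  }
  specs <- lapply(NODE_IDS, function(id) {
    level <- switch(id, level1 = 1L, chair_dir = 2L, stairs_dir = 2L, 3L)
    p <- if (inherits(params, "train_params")) params else params[[id]]
    node_spec(id, window_config = wc(level), params = p)
  })
  stats::setNames(specs, NODE_IDS)
}

# Trials and label level a node trains/evaluates on.
.node_scope <- function(node_id) {
  switch(node_id,
    level1            = list(activities = har_taxonomy()$activities, level = 1L),
    chair_dir         = list(activities = "chair", level = 2L),
    stairs_dir        = list(activities = c("stairs_up", "stairs_down"), level = 2L),
    stairs_up_phase   = list(activities = "stairs_up", level = 3L),
    stairs_down_phase = list(activities = "stairs_down", level = 3L),
    walking_phase     = list(activities = "walking", level = 3L))
}

#' Collect a node's labeled windows from a set of trials
#'
#' Segments the trials in the node's scope (e.g. only stair-ascent trials
#' for the ascending phase node) at the node's window configuration and
#' drops windows without a determinable label.
#'
#' @param trials list of `har_trial`s.
#' @param spec a [node_spec()].
#' @return A raw `window_set`.
#' @export
node_windows <- function(trials, spec) {
  sc <- .node_scope(spec$node_id)
  keep <- Filter(function(tr) tr$activity %in% sc$activities, trials)
  if (length(keep) == 0) stopf("no trials in scope for node %s", spec$node_id)
  sets <- lapply(keep, segment_trial, config = spec$window_config,
                 target_level = sc$level)
  ws <- ws_concat(sets)
  ws_subset(ws, which(!is.na(ws$label)))
}

#' Build an untrained node model
#'
#' Instantiates the node's convolutional network for `24 x W` inputs, where
#' `W` is the node's window width in samples: two convolutional layers for
#' the level-1 node, three for the others, kernels auto-shrunk to fit
#' narrow windows. Initial weights are drawn from the spec's seed, so two
#' builds from the same spec are identical.
#'
#' @param spec a [node_spec()].
#' @return Object of class `"har_node"` with the untrained network.
#' @export
build_node <- function(spec) {
  stopifnot(inherits(spec, "node_spec"))
  W <- spec$window_config$window_samples
  set.seed(spec$params$seed)
  net <- .net_new(24L, W, spec$conv_layers, spec$params$filters,
                  spec$params$dense_units, length(spec$classes),
                  spec$params$dropout_rate)
  structure(list(spec = spec, net = net, trained = FALSE),
            class = "har_node")
}

.ws_to_input <- function(ws) {
  d <- dim(ws$x)
  matrix(as.numeric(ws$x), d[1] * d[2], d[3]) / 255
}

.onehot <- function(labels, classes) {
  Y <- matrix(0, length(classes), length(labels))
  Y[cbind(match(labels, classes), seq_along(labels))] <- 1
  Y
}

#' Train a node on balanced, encoded window images
#'
#' Adam minimizes softmax cross-entropy over minibatches; a stratified
#' validation split drives early stopping (halt after `patience` epochs
#' without validation-loss improvement, keep the best epoch's parameters).
#' Fully reproducible under the spec's seed and a fixed input order.
#'
#' @param node an untrained [build_node()] result (or a [node_spec()],
#'   which is built first).
#' @param images an encoded `window_set` whose labels are exactly the
#'   node's classes; balance classes first with [balance_by_class()].
#' @return Object of class `"har_trained_node"` with the fitted parameters
#'   and a per-epoch training history.
#' @export
train_node <- function(node, images) {
  if (inherits(node, "node_spec")) node <- build_node(node)
  stopifnot(inherits(node, "har_node"), inherits(images, "window_set"))
  spec <- node$spec
  if (!isTRUE(attr(images, "encoded")))
    stopf("train_node expects encoded (0-255) window images")
  if (dim(images$x)[2] != spec$window_config$window_samples)
    stopf("window width %d does not match node config (%d samples)",
          dim(images$x)[2], spec$window_config$window_samples)
  bad <- setdiff(unique(images$label), spec$classes)
  if (length(bad))
    stopf("labels [%s] outside node classes", paste(bad, collapse = ", "))
  missing <- setdiff(spec$classes, unique(images$label))
  if (length(missing))
    stopf("class(es) [%s] absent from training images",
          paste(missing, collapse = ", "))

  X <- .ws_to_input(images)
  y <- images$label
  p <- spec$params
  set.seed(p$seed)
  net <- .net_new(24L, spec$window_config$window_samples, spec$conv_layers,
                  p$filters, p$dense_units, length(spec$classes),
                  p$dropout_rate)

  # stratified validation split
  val_idx <- unlist(lapply(spec$classes, function(cl) {
    ii <- which(y == cl)
    sample(ii, max(1L, floor(length(ii) * p$val_fraction)))
  }), use.names = FALSE)
  tr_idx <- setdiff(seq_along(y), val_idx)
  Xtr <- X[, tr_idx, drop = FALSE]; Ytr <- .onehot(y[tr_idx], spec$classes)
  Xva <- X[, val_idx, drop = FALSE]; Yva <- .onehot(y[val_idx], spec$classes)

  st <- .adam_init(net)
  best <- list(loss = Inf, net = net, epoch = 0L)
  wait <- 0L; t_step <- 0L
  hist <- list()
  for (epoch in seq_len(p$max_epochs)) {
    ord <- sample.int(ncol(Xtr))
    tr_loss <- 0; nb <- 0L
    for (b0 in seq(1L, length(ord), by = p$batch_size)) {
      bi <- ord[b0:min(b0 + p$batch_size - 1L, length(ord))]
      fw <- .net_forward(net, Xtr[, bi, drop = FALSE], train = TRUE)
      tr_loss <- tr_loss + .xent(fw$probs, Ytr[, bi, drop = FALSE])
      nb <- nb + 1L
      gr <- .net_backward(net, fw$caches, fw$probs, Ytr[, bi, drop = FALSE])
      t_step <- t_step + 1L
      up <- .adam_step(net, gr, st, p$learning_rate, t_step)
      net <- up$net; st <- up$st
    }
    va <- .net_forward(net, Xva, train = FALSE)
    va_loss <- .xent(va$probs, Yva)
    va_acc <- mean(apply(va$probs, 2, which.max) ==
                   apply(Yva, 2, which.max))
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                val_loss = va_loss, val_acc = va_acc)
    if (va_loss < best$loss - 1e-6) {
      best <- list(loss = va_loss, net = net, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= p$patience) break
    }
  }
  structure(list(spec = spec, net = best$net,
                 best_epoch = best$epoch,
                 history = do.call(rbind, hist)),
            class = "har_trained_node")
}

#' Predict class probabilities for window images
#'
#' @param trained a [train_node()] result.
#' @param images an encoded `window_set` (any number of windows) or a
#'   single 24 x W pixel matrix; the width must match the node's window
#'   configuration.
#' @return N x n_classes matrix of probabilities (rows sum to 1), columns
#'   named by the node's classes in their documented order.
#' @export
predict_node <- function(trained, images) {
  stopifnot(inherits(trained, "har_trained_node"))
  W <- trained$spec$window_config$window_samples
  if (inherits(images, "window_set")) {
    if (dim(images$x)[2] != W)
      stopf("image width %d does not match node window (%d samples)",
            dim(images$x)[2], W)
    X <- .ws_to_input(images)
  } else {
    images <- as.matrix(images)
    if (nrow(images) != 24 || ncol(images) != W)
      stopf("expected a 24 x %d image", W)
    X <- matrix(as.numeric(images), 24 * W, 1) / 255
  }
  fw <- .net_forward(trained$net, X, train = FALSE)
  probs <- t(fw$probs)
  colnames(probs) <- trained$spec$classes
  probs
}

#' @export
print.har_trained_node <- function(x, ...) {
  cat(sprintf("<har_trained_node> %s: classes [%s], best epoch %d\n",
              x$spec$node_id, paste(x$spec$classes, collapse = ", "),
              x$best_epoch))
  invisible(x)
}
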