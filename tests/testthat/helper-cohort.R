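# Shared fixtures, all generated in code at test time.

# short-duration signal params so cohort-level tests stay fast
quick_params <- function(activity, separation = 2.5, noise_sd = 0.05, ...) {
  dur <- switch(activity, chair = NA_real_, walking = 2.5, 2.8)
  signal_params(activity, duration_s = dur, separation = separation,
                noise_sd = noise_sd, ...)
}

quick_base_params <- function(separation = 2.5, noise_sd = 0.05) {
  acts <- har_taxonomy()$activities
  stats::setNames(lapply(acts, quick_params, separation = separation,
                         noise_sd = noise_sd), acts)
}

# a small cohort with short trials
tiny_cohort <- function(n = 2, battery = c(chair = 1, stairs_up = 1,
                                           stairs_down = 1, walking = 1),
                        seed = 42, separation = 2.5) {
  generate_cohort(cohort_spec(n, battery, rng_seed = seed),
                  quick_base_params(separation = separation))
}

# hand-built trial with fully controlled label tracks
mk_trial <- function(n, fs = 100, activity = "walking",
                     level1 = rep("walking", n),
                     level2 = rep(NA_character_, n),
                     level3 = rep(NA_character_, n),
                     channels = NULL) {
  structure(list(
    participant_id = "PX", trial_id = "TX", activity = activity,
    channels = channels %||% matrix(stats::rnorm(24 * n), 24, n,
                                    dimnames = list(channel_names(), NULL)),
    time_s = (seq_len(n) - 1) / fs,
    level1 = level1, level2 = level2, level3 = level3,
    start_s = 0, end_s = n / fs, sample_rate_hz = fs),
    class = "har_trial")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# two-class encoded window set, linearly separable by construction:
# class "a" images carry a hot stripe on channel 3, class "b" on channel 9
separable_images <- function(n_per_class = 150, W = 10, seed = 99) {
  set.seed(seed)
  mk <- function(n, hot) {
    x <- array(sample(0:60, 24 * W * n, TRUE), c(24, W, n))
    x[hot, , ] <- x[hot, , ] + 180
    x
  }
  ws <- structure(list(
    x = array(c(mk(n_per_class, 3), mk(n_per_class, 9)),
              c(24, W, 2 * n_per_class)),
    label = rep(c("a", "b"), each = n_per_class),
    start_s = numeric(2 * n_per_class),
    participant_id = rep("P", 2 * n_per_class),
    trial_id = rep("T", 2 * n_per_class),
    activity = rep("walking", 2 * n_per_class),
    level = 2L, config = window_config(2, 100, 10)),
    class = "window_set")
  attr(ws, "encoded") <- TRUE
  ws
}

# a node_spec over arbitrary classes for engine-level tests
two_class_spec <- function(W = 10, classes = c("a", "b"), ...) {
  sp <- node_spec("chair_dir",
                  window_config = window_config(2, W * 10, 10),
                  params = train_params(...))
  sp$classes <- classes
  sp
}

# small trained tree shared across hierarchy tests (built once per run)
.tree_cache <- new.env(parent = emptyenv())
shared_tree <- function() {
  if (is.null(.tree_cache$tree)) {
    ds <- tiny_cohort(n = 2, battery = c(chair = 2, stairs_up = 1,
                                         stairs_down = 1, walking = 1))
    wcfgs <- list(`1` = window_config(1, 200, 50),
                  `2` = window_config(2, 100, 20),
                  `3` = window_config(3, 40, 20))
    specs <- har_node_specs(wcfgs, train_params(
      max_epochs = 4, patience = 2, filters = c(8L, 16L), dense_units = 16L))
    .tree_cache$tree <- train_tree(ds$trials, specs, seed = 5)
    .tree_cache$dataset <- ds
  }
  .tree_cache
}
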