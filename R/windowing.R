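# Sliding-window segmentation and 0-255 image encoding.
#
# Each classification level uses its own fixed window size (defaults 200,
# 100 and 40 ms) slid in 10 ms increments over the trial; every extra slide
# increment a trial is longer than the window yields one extra training
# image (the window-based data augmentation). Windows are encoded as 24-row
# images by per-channel min-max normalization to the 0-255 range, with the
# normalization constants learned from the training fold only.

#' Window configuration for one classification level
#'
#' @param level classification level, 1, 2 or 3.
#' @param window_ms window size in milliseconds; defaults 200/100/40 ms for
#'   levels 1/2/3.
#' @param slide_ms slide increment in milliseconds (default 10).
#' @param sample_rate_hz sampling rate; `window_ms` and `slide_ms` must both
#'   correspond to whole numbers of samples at this rate.
#' @return Object of class `"window_config"` with the sizes in both
#'   milliseconds and samples.
#' @examples
#' window_config(1)           # 200 ms / 20 samples at 100 Hz
#' window_config(3, slide_ms = 20)
#' @export
window_config <- function(level, window_ms = c(200, 100, 40)[level],
                          slide_ms = 10, sample_rate_hz = 100) {
  stopifnot(level %in% 1:3, window_ms > 0, slide_ms > 0, sample_rate_hz > 0)
  if (window_ms < slide_ms)
    stopf("window_ms (%g) must be >= slide_ms (%g)", window_ms, slide_ms)
  w <- window_ms * sample_rate_hz / 1000
  s <- slide_ms * sample_rate_hz / 1000
  if (abs(w - round(w)) > 1e-9 || round(w) < 1)
    stopf("window_ms x sample_rate_hz must give a whole number of samples >= 1")
  if (abs(s - round(s)) > 1e-9 || round(s) < 1)
    stopf("slide_ms x sample_rate_hz must give a whole number of samples >= 1")
  structure(list(level = as.integer(level), window_ms = window_ms,
                 slide_ms = slide_ms, sample_rate_hz = sample_rate_hz,
                 window_samples = as.integer(round(w)),
                 slide_samples = as.integer(round(s))),
            class = "window_config")
}

#' Number of sliding windows in a trial
#'
#' `floor((L - W) / S) + 1` windows fit in a trial of length `L` for window
#' size `W` and slide `S` (all in milliseconds), and none when the trial is
#' shorter than the window. A 240 ms trial with a 200 ms window sliding
#' 10 ms yields 5 windows.
#'
#' @param trial_length_ms trial length in milliseconds (>= 0).
#' @param config a [window_config()].
#' @return Integer window count.
#' @examples
#' count_windows(240, window_config(1))  # 5
#' @export
count_windows <- function(trial_length_ms, config) {
  stopifnot(trial_length_ms >= 0)
  L <- trial_length_ms; W <- config$window_ms; S <- config$slide_ms
  if (L < W - 1e-9) return(0L)
  as.integer(floor((L - W) / S + 1e-9) + 1)
}

# window-majority label at a level: majority over labeled samples when at
# least half the window is labeled; tie breaks toward the label whose
# interval starts earlier within the window; NA when undetermined.
.window_label <- function(track_slice) {
  lab <- track_slice[!is.na(track_slice)]
  if (length(lab) * 2 < length(track_slice)) return(NA_character_)
  counts <- table(lab)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  first_pos <- vapply(top, function(l) which(track_slice == l)[1], numeric(1))
  top[which.min(first_pos)]
}

#' Segment a trial into labeled sliding windows
#'
#' Slides a fixed window over the trial and extracts the raw 24-channel
#' segments together with the label applicable at the requested level.
#' Windows fully or mostly outside labeled regions get label `NA`
#' (downstream training drops them); a window overlapping two label
#' intervals takes the majority label of its samples, with an exact tie
#' going to the earlier-starting label. Requesting a level the trial's
#' activity does not define (stance/swing on a chair trial, direction on a
#' walking trial) is an error.
#'
#' @param trial a `har_trial`.
#' @param config a [window_config()]; its sample rate must match the trial.
#' @param target_level level whose labels annotate the windows; defaults to
#'   `config$level`.
# Raw (unlabeled) sliding-window extraction; used directly at inference
# time where no label track may be consulted.
.segment_raw <- function(trial, config, target_level = config$level) {
  stopifnot(inherits(trial, "har_trial"), inherits(config, "window_config"))
  if (abs(config$sample_rate_hz - trial$sample_rate_hz) > 1e-6)
    stopf("config sample rate (%g) != trial sample rate (%g)",
          config$sample_rate_hz, trial$sample_rate_hz)
  n <- ncol(trial$channels)
  fs <- trial$sample_rate_hz
  N <- count_windows(n / fs * 1000, config)
  W <- config$window_samples; S <- config$slide_samples
  if (N == 0) {
    ws <- structure(list(
      x = array(numeric(0), dim = c(24, W, 0)), label = character(0),
      start_s = numeric(0), participant_id = character(0),
      trial_id = character(0), activity = character(0),
      level = as.integer(target_level), config = config),
      class = "window_set")
    attr(ws, "sample_idx") <- matrix(integer(0), W, 0)
    return(ws)
  }
  starts <- 1L + (seq_len(N) - 1L) * S
  idx <- outer(seq_len(W) - 1L, starts, "+")      # W x N sample indices
  x <- trial$channels[, as.vector(idx), drop = FALSE]
  dim(x) <- c(24L, W, N)
  dimnames(x) <- list(channel_names(), NULL, NULL)
  ws <- structure(list(
    x = x, label = rep(NA_character_, N),
    start_s = trial$start_s + (starts - 1L) / fs,
    participant_id = rep(trial$participant_id, N),
    trial_id = rep(trial$trial_id, N),
    activity = rep(trial$activity, N),
    level = as.integer(target_level), config = config),
    class = "window_set")
  attr(ws, "sample_idx") <- idx
  ws
}

#' Segment a trial into labeled sliding windows
#'
#' Slides a fixed window over the trial and extracts the raw 24-channel
#' segments together with the label applicable at the requested level.
#' Windows fully or mostly outside labeled regions get label `NA`
#' (downstream training drops them); a window overlapping two label
#' intervals takes the majority label of its samples, with an exact tie
#' going to the earlier-starting label. Requesting a level the trial's
#' activity does not define (stance/swing on a chair trial, direction on a
#' walking trial) is an error.
#'
#' @param trial a `har_trial`.
#' @param config a [window_config()]; its sample rate must match the trial.
#' @param target_level level whose labels annotate the windows; defaults to
#'   `config$level`.
#' @return A `"window_set"`: list with `x` (24 x W x N array), `label`
#'   (length-N character), `start_s`, `participant_id`, `trial_id`,
#'   `activity`, `level` and `config`.
#' @export
segment_trial <- function(trial, config, target_level = config$level) {
  if (target_level == 3 && trial$activity == "chair")
    stopf("the taxonomy defines no level-3 phases for chair trials")
  if (target_level == 2 && trial$activity == "walking")
    stopf("the taxonomy defines no level-2 classes for walking trials")
  ws <- .segment_raw(trial, config, target_level)
  idx <- attr(ws, "sample_idx")
  track <- switch(as.character(target_level),
                  "1" = trial$level1, "2" = trial$level2, "3" = trial$level3)
  ws$label <- vapply(seq_len(ncol(idx)),
                     function(i) .window_label(track[idx[, i]]), character(1))
  attr(ws, "sample_idx") <- NULL
  ws
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("<window_set> %d windows of %d samples, level %d%s\n",
              length(x$label), dim(x$x)[2], x$level,
              if (isTRUE(attr(x, "encoded"))) " (encoded 0-255)" else ""))
  invisible(x)
}

#' Subset or concatenate window sets
#'
#' @param ws a `window_set`.
#' @param idx integer indices of windows to keep.
#' @return A `window_set`.
#' @export
ws_subset <- function(ws, idx) {
  ws$x <- ws$x[, , idx, drop = FALSE]
  for (f in c("label", "start_s", "participant_id", "trial_id", "activity"))
    ws[[f]] <- ws[[f]][idx]
  ws
}

#' @rdname ws_subset
#' @param sets list of `window_set`s with identical level and window size.
#' @export
ws_concat <- function(sets) {
  sets <- Filter(function(s) length(s$label) > 0, sets)
  if (length(sets) == 0) stopf("nothing to concatenate")
  W <- dim(sets[[1]]$x)[2]
  for (s in sets) stopifnot(dim(s$x)[2] == W, s$level == sets[[1]]$level)
  out <- sets[[1]]
  out$x <- array(unlist(lapply(sets, function(s) s$x), use.names = FALSE),
                 dim = c(24, W, sum(vapply(sets, function(s) length(s$label), 0L))))
  for (f in c("label", "start_s", "participant_id", "trial_id", "activity"))
    out[[f]] <- unlist(lapply(sets, `[[`, f), use.names = FALSE)
  if (!is.null(attr(sets[[1]], "encoded")))
    attr(out, "encoded") <- attr(sets[[1]], "encoded")
  out
}

#' Fit per-channel normalization constants on a training set
#'
#' Records the minimum and maximum of every channel over all training
#' segments. The constants must come from the training fold only; held-out
#' data are encoded with the training constants (values beyond them clamp).
#'
#' @param ws a `window_set` of raw (unencoded) training segments.
#' @return Object of class `"normalization_stats"`: per-channel `min` and
#'   `max` (length-24 vectors).
#' @export
fit_normalization <- function(ws) {
  stopifnot(inherits(ws, "window_set"), length(ws$label) >= 1)
  m <- matrix(ws$x, nrow = 24)
  structure(list(min = apply(m, 1, min), max = apply(m, 1, max)),
            class = "normalization_stats")
}

# round half away from zero, so encodings are bit-reproducible across
# platforms (R's round() uses banker's rounding)
.round_half_away <- function(x) trunc(x + 0.5 * sign(x))

#' Encode raw segments as 0-255 window images
#'
#' Per channel `c`, pixel `= round(255 * (v - min_c) / (max_c - min_c))`
#' with round-half-away-from-zero, clamped to `[0, 255]`; a zero-range
#' channel maps to 0. Rows are the 24 channels in the fixed
#' [channel_names()] order; columns are time samples.
#'
#' @param ws a raw `window_set`.
#' @param stats [fit_normalization()] output from the training fold.
#' @return The `window_set` with `x` replaced by integer pixel values in
#'   `[0, 255]` and attribute `encoded = TRUE`.
#' @export
encode_windows <- function(ws, stats) {
  stopifnot(inherits(ws, "window_set"), inherits(stats, "normalization_stats"))
  rng <- stats$max - stats$min
  scale <- ifelse(rng > 0, 255 / rng, 0)
  d <- dim(ws$x)
  v <- (matrix(ws$x, nrow = 24) - stats$min) * scale
  px <- .round_half_away(v)
  px[px < 0] <- 0; px[px > 255] <- 255
  ws$x <- array(as.integer(px), dim = d,
                dimnames = list(channel_names(), NULL, NULL))
  attr(ws, "encoded") <- TRUE
  ws
}

#' Suggest a window size from an event-duration distribution
#'
#' The window size for a level is chosen from the distribution of event
#' durations: the 80th percentile of the durations, rounded down to a
#' multiple of the slide increment.
#'
#' @param durations_ms event durations in milliseconds.
#' @param slide_ms slide increment (default 10 ms).
#' @return Suggested window size in milliseconds.
#' @examples
#' suggest_window(c(100, 120, 200, 240, 400))
#' @export
suggest_window <- function(durations_ms, slide_ms = 10) {
  stopifnot(length(durations_ms) >= 1, all(durations_ms > 0))
  q <- stats::quantile(durations_ms, 0.8, names = FALSE, type = 7)
  max(slide_ms, floor(q / slide_ms) * slide_ms)
}
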