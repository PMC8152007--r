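# Core data types and I/O: per-sensor CSV reading/writing, magnetometer
# discard, trial assembly from interval labels, class balancing, and
# normalized cross-correlation time synchronization.

#' Construct a sensor stream
#'
#' One IMU's time-stamped recording: tri-axial accelerometer (g), gyroscope
#' (deg/s) and optionally magnetometer. Timestamps must be strictly
#' increasing and all present channels equal length.
#'
#' @param sensor_id one of `"left_thigh"`, `"left_shank"`, `"right_thigh"`,
#'   `"right_shank"`.
#' @param time_s numeric vector of sample times (seconds), strictly
#'   increasing.
#' @param acc,gyr n x 3 numeric matrices (columns x, y, z).
#' @param mag optional n x 3 magnetometer matrix, or `NULL`.
#' @return An object of class `"sensor_stream"`.
#' @export
sensor_stream <- function(sensor_id, time_s, acc, gyr, mag = NULL) {
  if (!sensor_id %in% SENSOR_IDS)
    stopf("unknown sensor_id '%s'", sensor_id)
  acc <- as.matrix(acc); gyr <- as.matrix(gyr)
  n <- length(time_s)
  if (any(diff(time_s) <= 0))
    stopf("sensor stream timestamps must be strictly increasing")
  if (nrow(acc) != n || nrow(gyr) != n || ncol(acc) != 3 || ncol(gyr) != 3)
    stopf("acc and gyr must be %d x 3 matrices", n)
  if (!is.null(mag)) {
    mag <- as.matrix(mag)
    if (nrow(mag) != n || ncol(mag) != 3)
      stopf("mag must be %d x 3 or NULL", n)
  }
  structure(list(sensor_id = sensor_id, time_s = as.numeric(time_s),
                 acc = unname(acc), gyr = unname(gyr),
                 mag = if (is.null(mag)) NULL else unname(mag)),
            class = "sensor_stream")
}

SENSOR_CSV_COLS <- c("time_s", "acc_x", "acc_y", "acc_z",
                     "gyr_x", "gyr_y", "gyr_z",
                     "mag_x", "mag_y", "mag_z")

#' Read / write a per-sensor CSV file
#'
#' The sensor CSV dialect has columns `time_s, acc_x, acc_y, acc_z, gyr_x,
#' gyr_y, gyr_z` and optionally `mag_x, mag_y, mag_z`. `read_sensor_csv()`
#' rejects files with non-monotone timestamps or an unexpected column set;
#' a missing magnetometer block is accepted. Writing then reading a stream
#' reproduces it to numeric precision.
#'
#' @param path file path.
#' @param sensor_id sensor identity to stamp on the stream (the dialect does
#'   not store it; it is carried by the file name / manifest).
#' @return `read_sensor_csv()` returns a [sensor_stream()];
#'   `write_sensor_csv()` returns `path` invisibly.
#' @export
read_sensor_csv <- function(path, sensor_id = "left_thigh") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  want7 <- SENSOR_CSV_COLS[1:7]
  if (!all(want7 %in% names(df)) ||
      !all(names(df) %in% SENSOR_CSV_COLS))
    stopf("unexpected sensor CSV columns in %s: got [%s], expected [%s] (mag optional)",
          path, paste(names(df), collapse = ", "),
          paste(SENSOR_CSV_COLS, collapse = ", "))
  has_mag <- all(SENSOR_CSV_COLS[8:10] %in% names(df))
  if (any(diff(df$time_s) <= 0))
    stopf("non-monotone timestamps in %s", path)
  sensor_stream(sensor_id, df$time_s,
                acc = as.matrix(df[, c("acc_x", "acc_y", "acc_z")]),
                gyr = as.matrix(df[, c("gyr_x", "gyr_y", "gyr_z")]),
                mag = if (has_mag) as.matrix(df[, c("mag_x", "mag_y", "mag_z")])
                      else NULL)
}

#' @rdname read_sensor_csv
#' @param stream a [sensor_stream()].
#' @export
write_sensor_csv <- function(stream, path) {
  stopifnot(inherits(stream, "sensor_stream"))
  df <- data.frame(time_s = stream$time_s,
                   acc_x = stream$acc[, 1], acc_y = stream$acc[, 2],
                   acc_z = stream$acc[, 3],
                   gyr_x = stream$gyr[, 1], gyr_y = stream$gyr[, 2],
                   gyr_z = stream$gyr[, 3])
  if (!is.null(stream$mag)) {
    df$mag_x <- stream$mag[, 1]; df$mag_y <- stream$mag[, 2]
    df$mag_z <- stream$mag[, 3]
  }
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discard magnetometer channels
#'
#' Magnetometer data are not used for model development and are dropped
#' before trial assembly. Accelerometer and gyroscope channels are left
#' untouched; the operation is idempotent.
#'
#' @param stream a [sensor_stream()].
#' @return The stream without its `mag` field.
#' @export
drop_magnetometer <- function(stream) {
  stopifnot(inherits(stream, "sensor_stream"))
  stream$mag <- NULL
  stream
}

# ---- Trial assembly -------------------------------------------------------

.labels_to_intervals <- function(trial) {
  fs <- trial$sample_rate_hz
  one <- function(track, level) {
    if (all(is.na(track))) return(NULL)
    r <- rle(ifelse(is.na(track), "<na>", track))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths
    keep <- r$values != "<na>"
    if (!any(keep)) return(NULL)
    data.frame(level = level, label = r$values[keep],
               start_s = trial$start_s + starts[keep] / fs,
               end_s = trial$start_s + ends[keep] / fs)
  }
  out <- rbind(one(trial$level1, 1L), one(trial$level2, 2L),
               one(trial$level3, 3L))
  cbind(data.frame(participant_id = trial$participant_id,
                   trial_id = trial$trial_id, activity = trial$activity),
        out)
}

#' Label intervals of a trial
#'
#' Run-length encodes a trial's per-sample label tracks into half-open
#' `[start_s, end_s)` intervals, the representation used by the labels CSV.
#'
#' @param trial a `har_trial`.
#' @return Data frame with columns `participant_id, trial_id, activity,
#'   level, label, start_s, end_s`.
#' @export
trial_intervals <- function(trial) .labels_to_intervals(trial)

#' Assemble a labeled trial from four sensor streams
#'
#' Crops the four streams to the trial bounds, stacks them into the fixed
#' 24-channel layout (sensors in [channel_names()] order, accelerometer
#' before gyroscope, x/y/z) and builds per-sample label tracks from the
#' interval rows. Intervals are half-open: sample `i` at time `t_i` belongs
#' to `[start_s, end_s)` iff `start_s <= t_i < end_s`. Labels outside the
#' taxonomy for the trial's activity (e.g. stance/swing on a chair trial)
#' are rejected, as are contradictory overlapping intervals at one level.
#'
#' @param streams list of exactly four [sensor_stream()]s, one per sensor,
#'   on a common time grid, magnetometer already discarded or present
#'   (ignored).
#' @param labels data frame of interval rows as produced by
#'   [trial_intervals()]; must contain a level-1 row whose label names the
#'   activity and whose bounds give the trial extent.
#' @param participant_id,trial_id identifiers for the assembled trial.
#' @return A `har_trial`.
#' @export
assemble_trial <- function(streams, labels, participant_id, trial_id) {
  ids <- vapply(streams, function(s) s$sensor_id, character(1))
  if (!setequal(ids, SENSOR_IDS) || anyDuplicated(ids))
    stopf("need each of [%s] exactly once; got [%s]",
          paste(SENSOR_IDS, collapse = ", "), paste(ids, collapse = ", "))
  streams <- streams[match(SENSOR_IDS, ids)]
  t0 <- streams[[1]]$time_s
  for (s in streams[-1])
    if (length(s$time_s) != length(t0) || max(abs(s$time_s - t0)) > 1e-6)
      stopf("sensor streams are not on a common time grid; synchronize first")

  l1 <- labels[labels$level == 1, , drop = FALSE]
  if (nrow(l1) < 1) stopf("labels must contain a level-1 interval")
  activity_lab <- unique(l1$label)
  if (length(activity_lab) != 1)
    stopf("conflicting level-1 labels: %s", paste(activity_lab, collapse = ", "))
  tax <- har_taxonomy()
  if (!activity_lab %in% tax$level1)
    stopf("unknown level-1 label '%s'", activity_lab)
  start_s <- min(l1$start_s); end_s <- max(l1$end_s)
  if (start_s < t0[1] - 1e-9 || end_s > t0[length(t0)] + 1 / 100 + 1e-9)
    stopf("label intervals extend beyond the stream time range")

  allowed <- list(
    `2` = switch(activity_lab, chair = tax$level2_chair,
                 stairs = tax$level2_stairs, walking = character(0)),
    `3` = if (activity_lab == "chair") character(0) else tax$level3)
  for (lv in c(2, 3)) {
    rows <- labels[labels$level == lv, , drop = FALSE]
    bad <- setdiff(rows$label, allowed[[as.character(lv)]])
    if (length(bad))
      stopf("level-%d label(s) [%s] not defined for activity '%s'",
            lv, paste(bad, collapse = ", "), activity_lab)
  }

  keep <- t0 >= start_s - 1e-9 & t0 < end_s - 1e-9
  time_s <- t0[keep]
  n <- length(time_s)
  X <- matrix(0, 24, n, dimnames = list(channel_names(), NULL))
  for (j in seq_along(streams)) {
    s <- streams[[j]]
    X[(j - 1) * 6 + (1:3), ] <- t(s$acc[keep, , drop = FALSE])
    X[(j - 1) * 6 + (4:6), ] <- t(s$gyr[keep, , drop = FALSE])
  }

  track <- function(lv) {
    rows <- labels[labels$level == lv, , drop = FALSE]
    out <- rep(NA_character_, n)
    for (i in seq_len(nrow(rows))) {
      sel <- time_s >= rows$start_s[i] - 1e-9 & time_s < rows$end_s[i] - 1e-9
      clash <- sel & !is.na(out) & out != rows$label[i]
      if (any(clash))
        stopf("contradictory overlapping level-%d intervals near %.3f s",
              lv, time_s[which(clash)[1]])
      out[sel] <- rows$label[i]
    }
    out
  }
  sim_act <- if (activity_lab == "stairs") {
    l2 <- stats::na.omit(unique(track(2)))
    if (length(l2) == 1 && l2 == "stairs_ascending") "stairs_up" else "stairs_down"
  } else activity_lab

  structure(list(
    participant_id = participant_id, trial_id = trial_id, activity = sim_act,
    channels = X, time_s = time_s - start_s,
    level1 = rep(activity_lab, n), level2 = track(2), level3 = track(3),
    start_s = 0, end_s = n / round(1 / stats::median(diff(time_s))),
    sample_rate_hz = round(1 / stats::median(diff(time_s)))
  ), class = "har_trial")
}

# ---- Balancing ------------------------------------------------------------

#' Balance a labeled collection by class
#'
#' Downsamples every class, without replacement, to the minimum class count.
#' The collection is shuffled before selection so repeated balancing draws
#' different subsets unless the seed is fixed.
#'
#' @param labels character/factor vector of class labels, one per item.
#' @param seed integer seed making the selection reproducible.
#' @return Integer vector of selected item indices (in shuffled order); its
#'   labels have equal class counts.
#' @examples
#' idx <- balance_by_class(c(rep("stance", 300), rep("swing", 180)), seed = 1)
#' table(c(rep("stance", 300), rep("swing", 180))[idx])
#' @export
balance_by_class <- function(labels, seed = 1L) {
  labels <- as.character(labels)
  if (length(labels) == 0) stopf("cannot balance an empty collection")
  counts <- table(labels)
  if (any(counts == 0)) stopf("empty class in input")
  m <- min(counts)
  set.seed(seed)
  perm <- sample.int(length(labels))
  picked <- unlist(lapply(names(counts), function(cl) {
    perm[labels[perm] == cl][seq_len(m)]
  }), use.names = FALSE)
  picked[sample.int(length(picked))]
}

# ---- Synchronization ------------------------------------------------------

#' Construct a reference orientation stream
#'
#' A high-rate (nominally 250 Hz) scalar reference signal used only for
#' time synchronization, e.g. an orientation-derived angular-velocity trace
#' recorded while the sensors were rotated about their X axis.
#'
#' @param time_s sample times, strictly increasing.
#' @param value numeric signal values.
#' @return Object of class `"reference_stream"`.
#' @export
reference_stream <- function(time_s, value) {
  if (any(diff(time_s) <= 0)) stopf("reference timestamps must increase")
  if (length(time_s) != length(value)) stopf("time and value lengths differ")
  structure(list(time_s = as.numeric(time_s), value = as.numeric(value)),
            class = "reference_stream")
}

# Normalized cross-correlation of two equal-rate series over integer-sample
# lags in [-max_lag, max_lag]. Pearson correlation of the overlapping
# segments at each lag; cross sums come from one FFT convolution, moment
# sums from cumulative sums. Positive lag means y lags x (y(t) ~ x(t-lag)).
.ncc_lags <- function(x, y, fs, max_lag_s) {
  nx <- length(x); ny <- length(y)
  L <- as.integer(floor(max_lag_s * fs))
  if (min(nx, ny) <= 2 * L)
    stopf("overlap too short for max_lag_s = %g at %g Hz", max_lag_s, fs)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("flat (zero-variance) input; normalized cross-correlation undefined")
  # R's convolve(a, b, "open") convolves a with rev(b); passing x unreversed
  # therefore yields correlation sums: conv[nx + k] = sum_i y_i x_{i-k}
  conv <- stats::convolve(y, x, type = "open")
  cx <- cumsum(x); cx2 <- cumsum(x^2)
  cy <- cumsum(y); cy2 <- cumsum(y^2)
  rng_sum <- function(cs, a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  lags <- (-L):L
  r <- vapply(lags, function(k) {
    ia <- max(1L, k + 1L); ib <- min(ny, nx + k)   # y overlap indices
    m <- ib - ia + 1L
    if (m < 8L) return(-Inf)
    sy <- rng_sum(cy, ia, ib);  sy2 <- rng_sum(cy2, ia, ib)
    sx <- rng_sum(cx, ia - k, ib - k); sx2 <- rng_sum(cx2, ia - k, ib - k)
    sxy <- conv[nx + k]
    vx <- sx2 - sx^2 / m; vy <- sy2 - sy^2 / m
    if (vx <= 1e-12 || vy <= 1e-12) return(-Inf)
    (sxy - sx * sy / m) / sqrt(vx * vy)
  }, numeric(1))
  list(lags = lags, r = r)
}

#' Estimate the time lag between a reference and a sensor stream
#'
#' Resamples the high-rate reference onto the sensor stream's sampling grid
#' by linear interpolation, then finds the integer-sample lag maximizing the
#' normalized cross-correlation (Pearson correlation of the mean-removed
#' overlapping segments at each candidate lag). Ties between equal maxima
#' break toward the smaller absolute lag. A positive lag means the sensor
#' stream's events occur later than the reference's.
#'
#' @param reference a [reference_stream()] (e.g. 250 Hz).
#' @param stream a [sensor_stream()] containing the synchronization motion,
#'   or a plain numeric vector already at the stream rate.
#' @param max_lag_s maximum |lag| searched, seconds. The overlapping
#'   duration must exceed `2 * max_lag_s`.
#' @param channel which stream channel carries the synchronization motion;
#'   default `"gyr_x"` (rotation about the sensor X axis).
#' @param sample_rate_hz required when `stream` is a bare numeric vector.
#' @return List with `lag_s` (seconds), `lag_samples`, and `correlation`
#'   (the normalized cross-correlation at the returned lag).
#' @export
synchronize <- function(reference, stream, max_lag_s = 2,
                        channel = "gyr_x", sample_rate_hz = NULL) {
  stopifnot(inherits(reference, "reference_stream"))
  if (inherits(stream, "sensor_stream")) {
    fs <- round(1 / stats::median(diff(stream$time_s)))
    mod <- substr(channel, 1, 3); ax <- match(substr(channel, 5, 5), c("x", "y", "z"))
    y <- stream[[mod]][, ax]
    t_y <- stream$time_s
  } else {
    if (is.null(sample_rate_hz))
      stopf("sample_rate_hz is required for a bare numeric stream")
    fs <- sample_rate_hz
    y <- as.numeric(stream)
    t_y <- (seq_along(y) - 1) / fs
  }
  # reference resampled onto the stream's rate over the reference's extent
  t_x <- seq(reference$time_s[1], reference$time_s[length(reference$time_s)],
             by = 1 / fs)
  x <- stats::approx(reference$time_s, reference$value, xout = t_x)$y
  res <- .ncc_lags(x, y, fs, max_lag_s)
  best <- max(res$r)
  cand <- which(res$r >= best - 1e-12)
  k <- res$lags[cand[which.min(abs(res$lags[cand]))]]
  # account for differing stream/reference start times
  offset <- t_y[1] - t_x[1]
  list(lag_s = k / fs + offset, lag_samples = k,
       correlation = res$r[match(k, res$lags)])
}
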