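# Writing a dataset to per-sensor CSV files + labels CSV + manifest, and
# reading one back through the sensor-stream / trial-assembly path.

.trial_to_streams <- function(trial, mag = TRUE) {
  t <- trial$time_s
  lapply(seq_along(SENSOR_IDS), function(j) {
    rows <- (j - 1) * 6
    m <- NULL
    if (mag) {
      # synthetic geomagnetic field trace: constant plus a slow sway; the
      # pipeline discards it before modelling
      m <- cbind(20 + 2 * sin(2 * pi * 0.2 * t + j),
                 5 + 1.5 * cos(2 * pi * 0.15 * t + j),
                 -43 + sin(2 * pi * 0.1 * t))
    }
    sensor_stream(SENSOR_IDS[j], t,
                  acc = t(trial$channels[rows + (1:3), , drop = FALSE]),
                  gyr = t(trial$channels[rows + (4:6), , drop = FALSE]),
                  mag = m)
  })
}

#' Write / read a cohort directory
#'
#' `write_cohort()` lays a dataset out as one CSV per sensor per trial
#' (`<trial_id>_<sensor>.csv` in the documented dialect, including a
#' synthetic magnetometer block), a `labels.csv` of half-open label
#' intervals and a `manifest.yaml`. `read_cohort()` reads it back through
#' [read_sensor_csv()], [drop_magnetometer()] and [assemble_trial()].
#'
#' @param dataset a `har_dataset`.
#' @param dir target directory (created if needed).
#' @param mag include synthetic magnetometer columns (default `TRUE`).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()`
#'   returns a `har_dataset`.
#' @export
write_cohort <- function(dataset, dir, mag = TRUE) {
  stopifnot(inherits(dataset, "har_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- list(); manifest <- list()
  for (trial in dataset$trials) {
    streams <- .trial_to_streams(trial, mag = mag)
    files <- vapply(streams, function(s) {
      f <- sprintf("%s_%s.csv", trial$trial_id, s$sensor_id)
      write_sensor_csv(s, file.path(dir, f))
      f
    }, character(1))
    labels[[trial$trial_id]] <- trial_intervals(trial)
    manifest[[trial$trial_id]] <- list(
      participant_id = trial$participant_id, activity = trial$activity,
      sample_rate_hz = trial$sample_rate_hz,
      files = as.list(stats::setNames(files, SENSOR_IDS)))
  }
  utils::write.csv(do.call(rbind, labels), file.path(dir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(participants = dataset$participants,
                        trials = manifest),
                   file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  man <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  labels <- utils::read.csv(file.path(dir, "labels.csv"))
  trials <- lapply(names(man$trials), function(tid) {
    info <- man$trials[[tid]]
    streams <- lapply(SENSOR_IDS, function(sid) {
      drop_magnetometer(read_sensor_csv(file.path(dir, info$files[[sid]]), sid))
    })
    assemble_trial(streams, labels[labels$trial_id == tid, , drop = FALSE],
                   participant_id = info$participant_id, trial_id = tid)
  })
  names(trials) <- names(man$trials)
  structure(list(trials = trials, participants = man$participants),
            class = "har_dataset")
}
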