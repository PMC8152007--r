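# Synthetic IMU cohort simulator.
#
# The simulator emulates the study conditions the classifiers assume: four
# 100 Hz IMUs on the left/right thigh and shank, a battery of chair
# sit-to-stand-to-sit transitions, 3-step stair ascents/descents and short
# self-paced walks, with per-sample activity labels, chair direction labels
# and stance/swing phase labels. Signals are sums of 2-3 harmonics of the
# movement cycle frequency with activity-specific amplitude signatures;
# gait activities carry a pi left-right phase offset (reciprocal limbs),
# chair transitions are bilaterally synchronized half-sine bursts.

GAIT_ACTIVITIES <- c("stairs_up", "stairs_down", "walking")

# Reference per-channel oscillation amplitudes by activity, in channel units
# (accelerometer g, gyroscope deg/s). Thigh/shank ratios differ by activity
# so activities are distinguishable; `separation` scales how far each
# activity's profile sits from the across-activity mean.
.amp_profile <- function(activity) {
  a <- switch(activity,
    walking     = c(acc_thigh = 0.25, acc_shank = 0.40, gyr_thigh = 60,  gyr_shank = 150),
    stairs_up   = c(acc_thigh = 0.38, acc_shank = 0.50, gyr_thigh = 95,  gyr_shank = 110),
    stairs_down = c(acc_thigh = 0.30, acc_shank = 0.60, gyr_thigh = 70,  gyr_shank = 130),
    chair       = c(acc_thigh = 0.30, acc_shank = 0.10, gyr_thigh = 90,  gyr_shank = 25)
  )
  per_sensor <- function(sensor) {
    thigh <- grepl("thigh", sensor)
    c(rep(if (thigh) a[["acc_thigh"]] else a[["acc_shank"]], 3),
      rep(if (thigh) a[["gyr_thigh"]] else a[["gyr_shank"]], 3))
  }
  out <- as.vector(vapply(SENSOR_IDS, per_sensor, numeric(6)))
  names(out) <- channel_names()
  # mild per-axis shaping so x/y/z are not identical
  out * rep(c(1, 0.8, 0.6, 1, 0.7, 0.5), times = 4)
}

.act_index <- function(activity) {
  match(activity, c("chair", "stairs_up", "stairs_down", "walking"))
}

#' Signal-model parameters for one activity
#'
#' Bundles the tunable parameters of the synthetic signal model for a single
#' activity: movement cycle duration, stance fraction for gait activities,
#' per-channel amplitude profile, relative noise level, per-participant
#' perturbation factors and the between-class separation scale.
#'
#' @param activity one of `"chair"`, `"stairs_up"`, `"stairs_down"`,
#'   `"walking"`.
#' @param cycle_duration_s movement cycle duration in seconds (gait stride
#'   or chair burst duration). Defaults: walking 1.1, stairs 1.4, chair 1.5.
#' @param stance_fraction fraction of each gait cycle spent in stance, in
#'   (0, 1). Ignored (with a warning) for chair trials. Defaults: walking
#'   0.62, stairs 0.60.
#' @param duration_s trial duration in seconds for gait trials (chair trial
#'   duration follows from the burst/gap structure). Defaults: walking 4.5,
#'   stairs 4.2.
#' @param n_transitions for chair trials, the number of alternating
#'   stand-up/sit-down bursts (a single sit-to-stand-to-sit is 2).
#' @param amplitude optional named 24-vector overriding the per-channel
#'   amplitude profile (accelerometer in g, gyroscope in deg/s).
#' @param noise_sd additive Gaussian noise, expressed as a fraction of each
#'   channel's reference amplitude; must be >= 0.
#' @param participant_sd standard deviation (log scale) of the log-normal
#'   multiplicative per-participant perturbation of amplitudes and cycle
#'   duration.
#' @param participant_shift named vector `c(amp = , dur = )` of
#'   multiplicative per-participant factors, normally filled in by
#'   [generate_cohort()].
#' @param separation non-negative scale of between-class signature
#'   differences; 0 collapses the gait classes onto a common signature and
#'   removes the stance/swing contrast.
#' @param sample_rate_hz sampling rate in Hz (default 100).
#' @return An object of class `"signal_params"`.
#' @examples
#' signal_params("walking", separation = 2)
#' @export
signal_params <- function(activity,
                          cycle_duration_s = NULL,
                          stance_fraction = NULL,
                          duration_s = NULL,
                          n_transitions = 2L,
                          amplitude = NULL,
                          noise_sd = 0.05,
                          participant_sd = 0.10,
                          participant_shift = c(amp = 1, dur = 1),
                          separation = 1,
                          sample_rate_hz = 100) {
  tax <- har_taxonomy()
  if (!activity %in% tax$activities)
    stopf("unknown activity '%s' (expected one of %s)", activity,
          paste(tax$activities, collapse = ", "))
  if (activity == "chair" && !is.null(stance_fraction)) {
    warnf("stance_fraction is ignored for chair trials")
    stance_fraction <- NULL
  }
  cycle_duration_s <- cycle_duration_s %||%
    switch(activity, walking = 1.1, stairs_up = 1.4, stairs_down = 1.4, chair = 1.5)
  if (activity != "chair")
    stance_fraction <- stance_fraction %||% switch(activity, walking = 0.62, 0.60)
  # gait defaults cover a whole number of cycles (4 strides / 3 stair
  # cycles), so the per-trial stance fraction is exact up to cycle-boundary
  # rounding regardless of the random start phase
  duration_s <- duration_s %||%
    switch(activity, walking = 4.4, stairs_up = 4.2, stairs_down = 4.2, chair = NA_real_)
  stopifnot(cycle_duration_s > 0, noise_sd >= 0, separation >= 0,
            sample_rate_hz > 0, n_transitions >= 1)
  if (!is.null(stance_fraction) &&
      (stance_fraction <= 0 || stance_fraction >= 1))
    stopf("stance_fraction must lie strictly between 0 and 1")
  structure(list(
    activity = activity, cycle_duration_s = cycle_duration_s,
    stance_fraction = stance_fraction, duration_s = duration_s,
    n_transitions = as.integer(n_transitions),
    amplitude = amplitude %||% .amp_profile(activity),
    noise_sd = noise_sd, participant_sd = participant_sd,
    participant_shift = participant_shift, separation = separation,
    sample_rate_hz = sample_rate_hz
  ), class = "signal_params")
}

# Across-activity mean of the gait profiles; the effective profile of a
# gait activity is mean + separation * (own - mean).
.gait_common <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      profs <- vapply(GAIT_ACTIVITIES, .amp_profile, numeric(24))
      cache <<- rowMeans(profs)
    }
    cache
  }
})

.effective_gait <- function(params) {
  common_amp <- .gait_common()
  amp <- common_amp + params$separation * (params$amplitude - common_amp)
  amp <- pmax(amp, 0.02 * params$amplitude + 1e-6)
  common_dur <- mean(c(1.1, 1.4, 1.4))
  dur <- common_dur + params$separation * (params$cycle_duration_s - common_dur)
  dur <- max(dur, 0.4)
  list(amp = amp * params$participant_shift[["amp"]],
       cycle = dur * params$participant_shift[["dur"]])
}

# Harmonic weights and phases, deterministic functions of channel, harmonic
# and activity so each class has a fixed signature.
.harmonic_weight <- function(ch, h, act_i, separation) {
  base <- c(1, 0.45, 0.2)[h]
  delta <- 0.35 * sin(0.7 * ch * h + 1.3 * act_i)
  base + separation * delta
}

.harmonic_phase <- function(ch, h, act_i) 0.4 * ch + 0.9 * h + 0.5 * act_i

# Gait trial: phase of limb L at time t is 2*pi*t/cycle + offset(L) + phi0;
# right limb offset 0, left limb offset pi (reciprocity). Stance of a limb
# is the first `stance_fraction` of its own cycle; the trial's level-3
# label track records the RIGHT limb's phase (documented convention).
.generate_gait <- function(params, n, fs) {
  eff <- .effective_gait(params)
  t <- (seq_len(n) - 1) / fs
  phi0 <- stats::runif(1, 0, 2 * pi)
  act_i <- .act_index(params$activity)
  frac <- function(x) x - floor(x)
  cyc <- t / eff$cycle + phi0 / (2 * pi)
  limb_frac <- list(left = frac(cyc + 0.5), right = frac(cyc))
  in_stance <- lapply(limb_frac, function(f) f < params$stance_fraction)

  ch_names <- channel_names()
  X <- matrix(0, nrow = 24, ncol = n, dimnames = list(ch_names, NULL))
  for (ch in seq_len(24)) {
    limb <- if (ch <= 12) "left" else "right"
    # mirrored signature index: the right limb shares the left limb's
    # per-channel waveform, offset by half a cycle (reciprocity)
    chm <- if (ch <= 12) ch else ch - 12L
    phase <- 2 * pi * cyc + if (limb == "left") pi else 0
    s <- 0
    for (h in 1:3) {
      s <- s + .harmonic_weight(chm, h, act_i, params$separation) *
        sin(h * phase + .harmonic_phase(chm, h, act_i))
    }
    amp <- eff$amp[ch]
    sig <- amp * s / 1.65   # keep peak magnitude near the reference amplitude
    # stance/swing contrast: the swinging limb's shank gyroscope swings
    # harder and its thigh accelerometer carries a DC shift
    swing <- !in_stance[[limb]]
    is_shank_gyr <- grepl("shank\\.gyr", ch_names[ch])
    is_thigh_acc <- grepl("thigh\\.acc", ch_names[ch])
    if (is_shank_gyr)
      sig[swing] <- sig[swing] * (1 + 0.6 * params$separation)
    if (is_thigh_acc)
      sig[swing] <- sig[swing] + 0.25 * params$separation * amp
    X[ch, ] <- sig
  }
  level3 <- ifelse(in_stance$right, "stance", "swing")
  list(X = X, level1 = rep(har_taxonomy()$activity_to_level1[[params$activity]], n),
       level2 = if (params$activity == "walking") rep(NA_character_, n)
                else rep(if (params$activity == "stairs_up") "stairs_ascending"
                         else "stairs_descending", n),
       level3 = level3)
}

# Chair trial: quiet lead-in, then alternating stand-up/sit-down half-sine
# bursts (starting with stand-up) separated by quiet gaps of 0.5-1.5 s,
# then a quiet tail. Both limbs move together (no left-right offset).
.generate_chair <- function(params, fs) {
  burst_s <- params$cycle_duration_s * params$participant_shift[["dur"]]
  k <- params$n_transitions
  gaps <- stats::runif(k - 1, 0.5, 1.5)
  lead <- 0.3; tail <- 0.3
  starts <- lead + c(0, cumsum(burst_s + gaps))
  total <- starts[k] + burst_s + tail
  n <- as.integer(round(total * fs))
  t <- (seq_len(n) - 1) / fs

  amp <- params$amplitude * params$participant_shift[["amp"]]
  act_i <- .act_index("chair")
  ch_names <- channel_names()
  X <- matrix(0, nrow = 24, ncol = n, dimnames = list(ch_names, NULL))
  level2 <- rep(NA_character_, n)
  dirs <- rep(c("stand_up", "sit_down"), length.out = k)
  for (j in seq_len(k)) {
    idx <- which(t >= starts[j] & t < starts[j] + burst_s)
    u <- (t[idx] - starts[j]) / burst_s
    bell <- sin(pi * u)
    sgn <- if (dirs[j] == "stand_up") 1 else -1
    for (ch in seq_len(24)) {
      chm <- if (ch <= 12) ch else ch - 12L   # bilateral symmetry
      shape <- bell * (1 + 0.3 * sin(2 * pi * u + .harmonic_phase(chm, 1, act_i)))
      X[ch, idx] <- X[ch, idx] + sgn * amp[ch] * shape
    }
    level2[idx] <- dirs[j]
  }
  list(X = X, level1 = rep("chair", n), level2 = level2,
       level3 = rep(NA_character_, n))
}

#' Generate one labeled synthetic trial
#'
#' Simulates a single activity execution as a 24-channel IMU recording with
#' per-sample labels at every taxonomy level the activity defines: level 1
#' always; chair direction (level 2) for chair trials; stance/swing
#' (level 3, right-limb convention) for gait trials. Additive Gaussian noise
#' is applied to every channel at `noise_sd` times its reference amplitude.
#'
#' @param activity activity name (see [har_taxonomy()]).
#' @param params a [signal_params()] object for that activity.
#' @param participant_id,trial_id identifiers stamped on the trial.
#' @param seed optional integer; when given, the RNG is seeded so the trial
#'   is exactly reproducible.
#' @return An object of class `"har_trial"`: list with `channels` (24 x n
#'   matrix in the [channel_names()] order), `time_s`, label tracks
#'   `level1`/`level2`/`level3`, `activity`, ids, bounds and sample rate.
#' @examples
#' tr <- generate_trial("walking", signal_params("walking"), "P01", "T1", seed = 1)
#' dim(tr$channels)
#' @export
generate_trial <- function(activity, params = signal_params(activity),
                           participant_id = "P01", trial_id = "T1",
                           seed = NULL) {
  tax <- har_taxonomy()
  if (!activity %in% tax$activities)
    stopf("unknown activity '%s'", activity)
  if (params$activity != activity)
    stopf("params were built for '%s', not '%s'", params$activity, activity)
  if (!is.null(seed)) set.seed(seed)
  fs <- params$sample_rate_hz

  if (activity == "chair") {
    gen <- .generate_chair(params, fs)
  } else {
    n <- as.integer(round(params$duration_s * fs))
    gen <- .generate_gait(params, n, fs)
  }
  n <- ncol(gen$X)
  noise_scale <- params$noise_sd * (abs(params$amplitude) + 1e-3)
  if (params$noise_sd > 0)
    gen$X <- gen$X + matrix(stats::rnorm(24 * n), 24, n) * noise_scale

  structure(list(
    participant_id = participant_id, trial_id = trial_id,
    activity = activity,
    channels = gen$X,
    time_s = (seq_len(n) - 1) / fs,
    level1 = gen$level1, level2 = gen$level2, level3 = gen$level3,
    start_s = 0, end_s = n / fs,
    sample_rate_hz = fs
  ), class = "har_trial")
}

#' Cohort specification
#'
#' @param n_participants number of participants (>= 2 so leave-one-out
#'   cross-validation is possible).
#' @param trials_per_activity named integer vector mapping activity to trial
#'   count; default is the full battery: 5 chair sit-to-stand-to-sit trials,
#'   3 stair ascents, 3 stair descents and 3 walks.
#' @param sample_rate_hz sampling rate (default 100 Hz).
#' @param rng_seed master seed for the cohort.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 18,
                        trials_per_activity = c(chair = 5, stairs_up = 3,
                                                stairs_down = 3, walking = 3),
                        sample_rate_hz = 100,
                        rng_seed = 1L) {
  if (n_participants < 2)
    stopf("n_participants must be >= 2 (leave-one-out needs at least 2 folds)")
  tax <- har_taxonomy()
  if (!all(names(trials_per_activity) %in% tax$activities))
    stopf("unknown activity in trials_per_activity")
  if (any(trials_per_activity < 1))
    stopf("all trial counts must be >= 1")
  stopifnot(sample_rate_hz > 0)
  structure(list(n_participants = as.integer(n_participants),
                 trials_per_activity = trials_per_activity,
                 sample_rate_hz = sample_rate_hz,
                 rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Generate a labeled synthetic cohort
#'
#' Generates the full activity battery for every participant. Each
#' participant receives one multiplicative log-normal perturbation of
#' amplitudes and cycle durations (drawn once from the master seed), so
#' leave-one-out folds differ; each trial additionally draws its own start
#' phase, gaps and noise from a trial-specific seed derived from the master
#' seed with [derive_seed()].
#'
#' @param spec a [cohort_spec()].
#' @param base_params optional named list mapping activity to
#'   [signal_params()]; defaults are built per activity at the cohort's
#'   sample rate.
#' @return An object of class `"har_dataset"`: list with `trials` (list of
#'   `har_trial`) and `participants`.
#' @examples
#' ds <- generate_cohort(cohort_spec(n_participants = 2,
#'   trials_per_activity = c(walking = 1), rng_seed = 7))
#' length(ds$trials)
#' @export
generate_cohort <- function(spec, base_params = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  acts <- names(spec$trials_per_activity)
  base_params <- base_params %||% stats::setNames(lapply(acts, function(a)
    signal_params(a, sample_rate_hz = spec$sample_rate_hz)), acts)

  pids <- sprintf("P%02d", seq_len(spec$n_participants))
  trials <- list()
  for (pid in pids) {
    set.seed(derive_seed(spec$rng_seed, "participant", pid))
    sd_p <- base_params[[acts[1]]]$participant_sd
    shift <- c(amp = stats::rlnorm(1, 0, sd_p), dur = stats::rlnorm(1, 0, sd_p))
    for (act in acts) {
      for (k in seq_len(spec$trials_per_activity[[act]])) {
        p <- base_params[[act]]
        p$participant_shift <- shift
        tid <- sprintf("%s_%s_%02d", pid, act, k)
        trials[[tid]] <- generate_trial(
          act, p, participant_id = pid, trial_id = tid,
          seed = derive_seed(spec$rng_seed, "trial", pid, act, k))
      }
    }
  }
  structure(list(trials = trials, participants = pids), class = "har_dataset")
}

#' @export
print.har_trial <- function(x, ...) {
  cat(sprintf("<har_trial> %s | %s | %s: %d samples @ %g Hz (%.2f s)\n",
              x$participant_id, x$trial_id, x$activity,
              ncol(x$channels), x$sample_rate_hz, x$end_s - x$start_s))
  invisible(x)
}

#' @export
print.har_dataset <- function(x, ...) {
  cat(sprintf("<har_dataset> %d trials, %d participants\n",
              length(x$trials), length(x$participants)))
  invisible(x)
}
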