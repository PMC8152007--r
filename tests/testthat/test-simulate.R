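# Synthetic cohort generator: label structure, phase budget, determinism.

test_that("gait trials honor the stance fraction within the phase budget", {
  # separation 1 keeps the effective cycle at its nominal duration; trials
  # spanning whole cycles make the stance budget exact up to boundary
  # rounding (two samples per cycle)
  for (act in c("walking", "stairs_up", "stairs_down")) {
    for (seed in c(11, 12, 13)) {
      p <- signal_params(act, noise_sd = 0, separation = 1)
      p$duration_s <- 3 * p$cycle_duration_s
      tr <- generate_trial(act, p, seed = seed)
      lab <- tr$level3
      expect_false(anyNA(lab))
      n_cycles <- (tr$end_s - tr$start_s) / p$cycle_duration_s
      tol <- 2 * n_cycles / length(lab)   # two samples per cycle
      expect_lt(abs(mean(lab == "stance") - p$stance_fraction), tol)
    }
  }
})

test_that("chair level-2 labels alternate stand-up/sit-down from stand-up", {
  p <- signal_params("chair", n_transitions = 5)
  tr <- generate_trial("chair", p, seed = 3)
  runs <- rle(tr$level2[!is.na(tr$level2)])$values
  expect_identical(runs, rep(c("stand_up", "sit_down"), length.out = 5))
  expect_true(all(is.na(tr$level3)))
})

test_that("label tracks exist exactly where the taxonomy defines them", {
  for (act in har_taxonomy()$activities) {
    tr <- generate_trial(act, quick_params(act), seed = 2)
    expect_false(anyNA(tr$level1))
    expect_identical(unique(tr$level1),
                     unname(har_taxonomy()$activity_to_level1[act]))
    if (act == "walking") expect_true(all(is.na(tr$level2)))
    if (act == "chair") expect_true(all(is.na(tr$level3)))
    if (act %in% c("stairs_up", "stairs_down"))
      expect_false(anyNA(tr$level2))
  }
})

test_that("gait limbs are reciprocal and chair limbs synchronized", {
  # with separation = 0 the stance/swing modulation vanishes, so the left
  # limb equals the right limb advanced by exactly half a cycle
  p <- signal_params("walking", stance_fraction = 0.6, noise_sd = 0,
                     separation = 0)
  tr <- generate_trial("walking", p, seed = 8)
  # separation 0 collapses every gait class onto the common cycle duration
  half <- as.integer(round(mean(c(1.1, 1.4, 1.4)) / 2 * p$sample_rate_hz))
  l <- tr$channels["left_shank.gyr_y", ]
  r <- tr$channels["right_shank.gyr_y", ]
  n <- length(l) - half
  expect_gt(stats::cor(l[seq_len(n)], r[seq_len(n) + half]), 0.99)

  ch <- generate_trial("chair", signal_params("chair", noise_sd = 0), seed = 8)
  expect_equal(ch$channels["left_thigh.gyr_x", ],
               ch$channels["right_thigh.gyr_x", ], tolerance = 1e-12)
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_trial("walking", quick_params("walking"), seed = 7)
  b <- generate_trial("walking", quick_params("walking"), seed = 7)
  expect_identical(a$channels, b$channels)
  d1 <- tiny_cohort(seed = 13)
  d2 <- tiny_cohort(seed = 13)
  expect_identical(d1, d2)
  d3 <- tiny_cohort(seed = 14)
  expect_false(identical(d1$trials[[1]]$channels, d3$trials[[1]]$channels))
})

test_that("the full battery yields n_participants x 14 trials", {
  ds <- generate_cohort(cohort_spec(n_participants = 18, rng_seed = 1),
                        quick_base_params())
  expect_length(ds$trials, 18 * (5 + 3 + 3 + 3))
  expect_length(ds$participants, 18)
  small <- generate_cohort(cohort_spec(2, c(walking = 1), rng_seed = 1),
                           quick_base_params())
  expect_length(small$trials, 2)
  expect_length(unique(vapply(small$trials, `[[`, "", "participant_id")), 2)
})

test_that("invalid simulator inputs are rejected by name", {
  expect_error(signal_params("jogging"), "unknown activity")
  expect_error(generate_trial("jogging"), "unknown activity")
  expect_warning(signal_params("chair", stance_fraction = 0.6),
                 "ignored for chair")
  expect_error(cohort_spec(n_participants = 1), ">= 2")
  expect_error(cohort_spec(2, c(walking = 0)), ">= 1")
  expect_error(signal_params("walking", stance_fraction = 1.2),
               "between 0 and 1")
})
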