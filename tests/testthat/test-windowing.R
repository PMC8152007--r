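# Sliding-window counts, segmentation, boundary labeling, 0-255 encoding.

test_that("window counts follow floor((L - W)/S) + 1", {
  cfg <- window_config(1)           # 200 ms window, 10 ms slide
  expect_identical(count_windows(240, cfg), 5L)
  expect_identical(count_windows(200, cfg), 1L)
  expect_identical(count_windows(199, cfg), 0L)
  expect_identical(count_windows(0, cfg), 0L)
})

test_that("segment counts agree with brute-force window-start enumeration", {
  set.seed(31)
  for (i in 1:40) {
    W_samp <- sample(2:40, 1)
    S_samp <- sample(1:W_samp, 1)
    n <- sample(1:300, 1)
    cfg <- window_config(1, W_samp * 10, S_samp * 10)
    # oracle: enumerate starts whose window fits in the trial
    brute <- sum((seq_len(max(n, 1)) - 1) %% S_samp == 0 &
                 (seq_len(max(n, 1)) - 1) + W_samp <= n)
    expect_identical(count_windows(n * 10, cfg), as.integer(brute))
    tr <- mk_trial(n)
    ws <- segment_trial(tr, cfg, target_level = 1)
    expect_identical(length(ws$label), as.integer(brute))
  }
})

test_that("a 6 s walking trial yields 597 level-3 windows at defaults", {
  tr <- generate_trial("walking",
                       signal_params("walking", duration_s = 6), seed = 1)
  ws <- segment_trial(tr, window_config(3))
  expect_length(ws$label, 597)   # floor((6000 - 40)/10) + 1
})

test_that("longer trials never yield fewer windows", {
  cfg <- window_config(2, 100, 30)
  counts <- vapply(seq(0, 2000, by = 70), count_windows, integer(1),
                   config = cfg)
  expect_true(all(diff(counts) >= 0))
})

test_that("boundary windows take the majority label, ties go earlier", {
  n <- 100
  lv3 <- c(rep("stance", 50), rep("swing", 50))
  tr <- mk_trial(n, level3 = lv3)
  cfg <- window_config(3, 40, 10)   # 4-sample windows
  ws <- segment_trial(tr, cfg)
  # window at 0.48 s covers samples 49:52 -> 2 stance, 2 swing: an exact
  # tie, and the earlier-starting label (stance) wins
  expect_identical(ws$label[which(abs(ws$start_s - 0.48) < 1e-9)], "stance")
  # fully inside one interval -> that label
  expect_identical(ws$label[1], "stance")
  expect_identical(ws$label[length(ws$label)], "swing")
  # majority: window at 0.49 s covers samples 50:53 -> 3 swing
  expect_identical(ws$label[which(abs(ws$start_s - 0.49) < 1e-9)], "swing")

  # unlabeled regions yield NA labels
  lv3_gap <- c(rep("stance", 20), rep(NA_character_, 60), rep("swing", 20))
  ws2 <- segment_trial(mk_trial(n, level3 = lv3_gap), cfg)
  expect_true(anyNA(ws2$label))
  expect_length(ws2$label, count_windows(n * 10, cfg))
})

test_that("taxonomy-violating segmentation requests are rejected", {
  chair <- generate_trial("chair", quick_params("chair"), seed = 1)
  expect_error(segment_trial(chair, window_config(3)), "no level-3")
  walk <- generate_trial("walking", quick_params("walking"), seed = 1)
  expect_error(segment_trial(walk, window_config(2)), "no level-2")
})

test_that("encoding maps the training range onto 0-255 exactly", {
  W <- 4
  x <- array(0, c(24, W, 2))
  x[1, , 1] <- -1; x[1, , 2] <- 1      # channel 1 spans [-1, 1]
  x[2, , ] <- 3.2                      # constant channel
  ws <- structure(list(x = x, label = c("a", "b"), start_s = c(0, 1),
                       participant_id = c("P", "P"), trial_id = c("T", "T"),
                       activity = c("walking", "walking"), level = 1L,
                       config = window_config(1, 40, 10)),
                  class = "window_set")
  st <- fit_normalization(ws)
  expect_identical(st$min[1], -1); expect_identical(st$max[1], 1)
  expect_identical(st$min[2], 3.2); expect_identical(st$max[2], 3.2)

  enc <- encode_windows(ws, st)
  expect_identical(unique(as.vector(enc$x[1, , 1])), 0L)     # v = min -> 0
  expect_identical(unique(as.vector(enc$x[1, , 2])), 255L)   # v = max -> 255
  expect_identical(unique(as.vector(enc$x[2, , ])), 0L)      # zero range -> 0
  # v = 0 in [-1, 1]: 127.5 rounds half away from zero to 128
  ws$x[1, 1, 1] <- 0
  enc2 <- encode_windows(ws, st)
  expect_identical(unname(enc2$x[1, 1, 1]), 128L)
  # out-of-range test values clamp
  ws$x[1, 1, 1] <- 57
  expect_identical(unname(encode_windows(ws, st)$x[1, 1, 1]), 255L)
  ws$x[1, 1, 1] <- -57
  expect_identical(unname(encode_windows(ws, st)$x[1, 1, 1]), 0L)
})

test_that("encoding is invariant to affine channel transforms and in range", {
  tr <- generate_trial("walking", quick_params("walking"), seed = 6)
  cfg <- window_config(2, 100, 50)
  ws <- segment_trial(tr, cfg, target_level = 1)
  enc_a <- encode_windows(ws, fit_normalization(ws))
  # affinely transform one channel across the whole training set
  ws_b <- ws
  ws_b$x[5, , ] <- 3.7 * ws_b$x[5, , ] - 11
  enc_b <- encode_windows(ws_b, fit_normalization(ws_b))
  expect_identical(enc_a$x, enc_b$x)
  expect_true(all(enc_a$x >= 0 & enc_a$x <= 255))
})

test_that("suggest_window floors the 80th percentile to a slide multiple", {
  durs <- c(100, 120, 200, 240, 400)
  q <- stats::quantile(durs, 0.8, names = FALSE)
  expect_identical(suggest_window(durs, 10), floor(q / 10) * 10)
  expect_identical(suggest_window(c(5, 6, 7), 10), 10)   # floor at one slide
})
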