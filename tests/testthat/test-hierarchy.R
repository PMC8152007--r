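# Decision-tree dispatch, overlap resolution, per-trial aggregation.

test_that("a trained tree routes synthetic trials to the right activities", {
  tc <- shared_tree()
  tree <- tc$tree
  expect_setequal(names(tree$nodes),
                  c("level1", "chair_dir", "stairs_dir", "stairs_up_phase",
                    "stairs_down_phase", "walking_phase"))
  # high-separation chair trial: level-1 mode is chair
  chair <- generate_trial("chair", quick_params("chair"), "P9", "C9", seed = 77)
  dec <- classify_windows(tree, chair)
  agg <- aggregate_trial(dec)
  expect_identical(agg[["1"]]$label, "chair")
  expect_gt(agg[["1"]]$support, 0.5)
  # conservation: level-1 decisions = count_windows(trial length)
  n1 <- sum(dec$level == 1)
  expect_identical(n1, count_windows((chair$end_s - chair$start_s) * 1000,
                                     tree$specs$level1$window_config))
  # counts per level sum to the number of decisions at that level
  expect_identical(sum(agg[["1"]]$counts), n1)
})

test_that("every decision stays inside the taxonomy with a consistent path", {
  tc <- shared_tree()
  walk <- generate_trial("walking", quick_params("walking"), "P9", "W9",
                         seed = 78)
  dec <- classify_windows(tc$tree, walk)
  tax <- har_taxonomy()
  all_labels <- c(tax$level1, tax$level2_chair, tax$level2_stairs, tax$level3)
  expect_true(all(dec$predicted %in% all_labels))
  # path consistency: each row's path ends with its own prediction and
  # starts with a level-1 class
  expect_true(all(vapply(seq_len(nrow(dec)), function(i) {
    parts <- strsplit(dec$path[i], "/", fixed = TRUE)[[1]]
    parts[length(parts)] == dec$predicted[i] && parts[1] %in% tax$level1
  }, logical(1))))
  # level-2/3 decisions fall inside a level-1 span predicting their root
  d1 <- dec[dec$level == 1, ]
  for (i in which(dec$level > 1)) {
    root <- strsplit(dec$path[i], "/", fixed = TRUE)[[1]][1]
    covering <- d1$predicted[d1$start_s <= dec$start_s[i] + 1e-9 &
                             d1$end_s >= dec$end_s[i] - 1e-9]
    expect_true(root %in% covering || length(covering) == 0)
  }
})

test_that("probabilities and spans drive overlap resolution", {
  row <- function(pred, prob, node = "walking_phase", s = 1, e = 1.04)
    data.frame(participant_id = "P", trial_id = "T", node_id = node,
               level = 3, start_s = s, end_s = e, predicted = pred,
               probability = prob, path = paste0("walking/", pred))
  a <- row("stance", 0.81); b <- row("swing", 0.64)
  expect_identical(resolve_overlap(a, b)$predicted, "stance")
  expect_identical(resolve_overlap(b, a)$predicted, "stance")
  # exact tie: earlier class in the node's order wins, and is logged
  expect_message(r <- resolve_overlap(row("swing", 0.5), row("stance", 0.5)),
                 "tie")
  expect_identical(r$predicted, "stance")
  # identical decisions resolve to themselves
  expect_identical(resolve_overlap(a, a), a)
  expect_error(resolve_overlap(a, row("swing", 0.6, s = 2, e = 2.04)),
               "different spans")
})

test_that("aggregation reports modal labels and supports", {
  dec <- data.frame(level = 1,
                    predicted = c(rep("walking", 7), rep("stairs", 3)))
  agg <- aggregate_trial(dec)
  expect_identical(agg[["1"]]$label, "walking")
  expect_equal(agg[["1"]]$support, 0.7)
  expect_identical(sum(agg[["1"]]$counts), 10L)
  same <- data.frame(level = 3, predicted = rep("stance", 5))
  expect_equal(aggregate_trial(same)[["3"]]$support, 1)
  expect_error(aggregate_trial(data.frame()), "no decisions")
})

test_that("missing child models and too-short trials are handled", {
  tc <- shared_tree()
  crippled <- tc$tree
  crippled$nodes$walking_phase <- NULL
  walk <- generate_trial("walking", quick_params("walking"), "P9", "W10",
                         seed = 79)
  expect_error(classify_windows(crippled, walk), "walking_phase")
  stub <- generate_trial("walking",
                         signal_params("walking", duration_s = 0.1), seed = 1)
  expect_warning(dec <- classify_windows(tc$tree, stub), "shorter")
  expect_identical(nrow(dec), 0L)
})
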