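test_that("window partition tiles the epoch without overlap", {
  w <- window_partition(-500, 4300, 80)
  expect_equal(nrow(w), 60L)
  expect_equal(w$start[1], -500)
  expect_true(all(diff(w$start) == 80))
  expect_equal(nrow(window_partition(0, 400, 80)), 5L)
  expect_equal(nrow(window_partition(0, 79, 80)), 0L)   # no partial windows
  expect_error(window_partition(0, 100, 0), class = "invalid_parameter_error")
})

test_that("noise-free time course hits the analytic square in active windows", {
  tt <- generate_design(design_spec(reps_per_cell = 2), seed = 11)
  g <- goal_square_geometry(n_channels = 12, snr = NULL,
                            activation = activation_profile("delay1"), seed = 11)
  ep <- generate_epochs(tt, list(goal = g), n_channels = 12, noise_sd = 0,
                        seed = 11)
  lab <- goal_labels(tt)
  tc1 <- timecourse_circularity(ep, lab, n_resamples = 1, seed = 1)
  tc10 <- timecourse_circularity(ep, lab, n_resamples = 10, seed = 2)
  expect_equal(length(tc1$values), 60L)
  # resampling is irrelevant without noise
  expect_equal(tc1$values, tc10$values, tolerance = 1e-12)
  active <- tc1$window_centers > 440 & tc1$window_centers < 1660
  inactive <- tc1$window_centers < -60
  expect_true(all(abs(tc1$values[active] - pi / 4) < 1e-9))
  expect_true(all(tc1$values[inactive] == 0))
})

test_that("compiled and reference engines agree", {
  tt <- generate_design(design_spec(reps_per_cell = 1), seed = 3)
  g <- goal_square_geometry(n_channels = 8, snr = NULL, seed = 3)
  ep <- generate_epochs(tt, list(goal = g), n_channels = 8, noise_sd = 0,
                        seed = 3)
  wm <- geomstate:::window_means(ep, window_partition(-500, 4300, 80))
  lab <- goal_labels(tt)
  expect_equal(geomstate:::tc_engine(wm, lab, 1L),
               geomstate:::tc_engine_r(wm, lab, 1L), tolerance = 1e-12)
})

test_that("cluster test recovers a planted Delay-1 cluster", {
  tt <- generate_design(seed = 21)
  lab <- goal_labels(tt)
  g <- goal_square_geometry(n_channels = 16, snr = 1,
                            activation = activation_profile("delay1"), seed = 21)
  ep <- generate_epochs(tt, list(goal = g), n_channels = 16, noise_sd = 1,
                        seed = 21)
  tc <- timecourse_circularity(ep, lab, n_resamples = 5, seed = 1)
  nn <- permutation_null(ep, lab, n_perm = 300, n_resamples = 5, seed = 2)
  cl <- cluster_test(tc, nn)
  expect_s3_class(cl, "cluster_set")
  sig <- cl$clusters[cl$significant, , drop = FALSE]
  expect_gte(nrow(sig), 1L)
  # significant windows overlap the planted 400-1700 ms epoch only
  w <- tc$windows
  for (i in seq_len(nrow(sig))) {
    expect_true(w$end[sig$start[i]] > 400 - 80)
    expect_true(w$start[sig$end[i]] < 1700 + 80)
  }
})

test_that("permutation null is deterministic and shaped correctly", {
  tt <- generate_design(design_spec(reps_per_cell = 1), seed = 31)
  g <- goal_square_geometry(n_channels = 6, snr = 0.5, seed = 31)
  ep <- generate_epochs(tt, list(goal = g), n_channels = 6, seed = 31)
  lab <- goal_labels(tt)
  expect_warning(n2 <- permutation_null(ep, lab, n_perm = 2, n_resamples = 1,
                                        seed = 5))
  expect_equal(dim(n2), c(2L, 60L))
  suppressWarnings({
    a <- permutation_null(ep, lab, n_perm = 5, n_resamples = 2, seed = 7)
    b <- permutation_null(ep, lab, n_perm = 5, n_resamples = 2, seed = 7)
  })
  expect_identical(a, b)
})

test_that("an all-null curve yields no clusters", {
  set.seed(41)
  null <- matrix(runif(200 * 20), 200, 20)
  flat <- rep(-1, 20)    # below every pointwise threshold
  cl <- cluster_test(flat, null)
  expect_equal(nrow(cl$clusters), 0L)
  expect_error(cluster_test(rep(0, 10), null),
               class = "incompatible_timecourse_error")
})

test_that("combined error matches a hand computation", {
  tt <- data.frame(size_error = c(0.1, -0.2, 0.05, 0.3),
                   color_error = c(-4, 2, 8, -1))
  ce <- combined_error(tt)
  hand <- as.numeric(scale(abs(tt$size_error))) + as.numeric(scale(abs(tt$color_error)))
  expect_equal(ce, hand, tolerance = 1e-12)
  # sign of the raw error is irrelevant
  tt2 <- tt
  tt2$size_error <- -tt2$size_error
  expect_equal(combined_error(tt2), ce, tolerance = 1e-12)
  # zero-variance guard returns the informative component
  tt3 <- tt
  tt3$size_error <- 0.1
  expect_warning(ce3 <- combined_error(tt3))
  expect_equal(ce3, as.numeric(scale(abs(tt3$color_error))), tolerance = 1e-12)
})

test_that("trial-split difference is antisymmetric in the split labels", {
  tt <- generate_design(design_spec(reps_per_cell = 2), seed = 51)
  lab <- goal_labels(tt)
  g <- goal_square_geometry(n_channels = 8, snr = 1, seed = 51)
  ep <- generate_epochs(tt, list(goal = g), n_channels = 8, seed = 51)
  tt <- generate_behavior(tt, seed = 51)
  ce <- combined_error(tt)
  a <- trial_split_difference(ep, lab, ce, n_perm = 30, seed = 1)
  b <- trial_split_difference(ep, lab, -ce, n_perm = 30, seed = 1)
  expect_equal(a$diff_timecourse, -b$diff_timecourse, tolerance = 1e-9)
  expect_length(intersect(a$good_trials, a$bad_trials), 0L)
})

test_that("split recovery: coupling produces a positive good-bad difference", {
  tt <- generate_design(seed = 61)
  lab <- goal_labels(tt)
  set.seed(61)
  gain <- runif(nrow(tt), 0.1, 1.9)
  # low per-sample SNR: 80-ms window averaging still leaves the weak-gain
  # quartile below the recovery ceiling, so the split difference is visible
  g <- goal_square_geometry(n_channels = 12, snr = 0.01,
                            activation = activation_profile("delay1"), seed = 61)
  ep <- generate_epochs(tt, list(goal = g), n_channels = 12, noise_sd = 1,
                        trial_gain = gain, seed = 61)
  tt <- generate_behavior(tt, strength = gain, coupling = 0.8, noise_sd = 0.1,
                          seed = 61)
  sp <- trial_split_difference(ep, lab, combined_error(tt), n_perm = 200,
                               alternative = "greater", seed = 2)
  act <- sp$window_centers > 400 & sp$window_centers < 1700
  expect_gt(mean(sp$diff_timecourse[act]), 0)
  sig <- sp$clusters$clusters[sp$clusters$significant, , drop = FALSE]
  expect_gte(nrow(sig), 1L)
})

test_that("quartile splits that cannot cover all conditions are rejected", {
  tt <- generate_design(design_spec(reps_per_cell = 1), seed = 71)
  g <- stimulus_grid_geometry(n_channels = 8, seed = 71)
  ep <- generate_epochs(tt, list(stimulus = g), n_channels = 8, seed = 71)
  tt <- generate_behavior(tt, seed = 71)
  # 6-condition stimulus labels with 1 rep per cell: quartiles cannot cover
  expect_error(
    trial_split_difference(ep, stimulus_labels(tt), combined_error(tt),
                           rule = "quartile", order_label = "stimulus_hex",
                           n_perm = 10, seed = 1),
    class = "split_coverage_error")
})

test_that("behavior correlations apply BH within the defined family", {
  # perfectly monotone pairing: rho = -1, single-test adjustment is identity
  circ <- data.frame(delay1 = c(5, 4, 3, 2, 1, 0))
  err <- 1:6
  out <- behavior_correlation(circ, err)
  expect_equal(out$rho, -1)
  expect_equal(out$p_adj, out$p)

  # hand-checked BH on a 4-test family (p = .01, .02, .04, .8):
  # adjusted = (.04, .04, .0533, .8), so two tests pass q = .05
  p <- c(0.01, 0.02, 0.04, 0.8)
  hand <- rev(cummin(rev(p * 4 / seq_len(4))))
  expect_equal(stats::p.adjust(p, "BH"), hand, tolerance = 1e-12)
  expect_equal(sum(hand <= 0.05), 2L)

  # constant columns are excluded from the family
  circ2 <- data.frame(a = c(1, 2, 3, 4, 5, 6), b = rep(2, 6))
  out2 <- behavior_correlation(circ2, err)
  expect_false(out2$defined[out2$cell == "b"])
  expect_true(is.na(out2$p_adj[out2$cell == "b"]))
})

test_that("motor relabeling follows the sign rule and excludes ties", {
  tt <- data.frame(trial_id = 1:3,
                   size_start = c(10, 10, 10), color_start = c(50, 50, 50),
                   response_size = c(14, 8, 10), response_color = c(44, 60, 55))
  suppressMessages(lab <- motor_relabel(tt))
  expect_equal(as.character(lab), c("bigger_greener", "smaller_redder", NA))
  expect_equal(attr(lab, "excluded"), 3L)
})

test_that("motor directions are independent of the cued goal", {
  tt <- generate_design(seed = 81)
  tt <- generate_behavior(tt, seed = 81)
  ml <- motor_relabel(tt)
  keep <- !is.na(ml)
  tab <- table(goal_labels(tt)[keep], ml[keep])
  out <- independence_test(tab)
  # textbook chi-square statistic oracle
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(unname(out$statistic), sum((tab - E)^2 / E), tolerance = 1e-9)
  expect_gt(out$p.value, 0.001)   # no association with the cued goal
})

test_that("incorrect-goal relabeling returns exactly the mismatched trials", {
  # error-free responses sit exactly on the target: no mismatches
  tt <- generate_design(design_spec(reps_per_cell = 1), seed = 91)
  ok <- incorrect_goal_relabel(tt)
  expect_equal(nrow(ok), 0L)
  expect_true(attr(ok, "empty"))

  # hand-built mismatches: push two responses past the stimulus value
  tt2 <- tt[1:6, ]
  tt2$goal_size <- "bigger"; tt2$goal_color <- "redder"
  tt2$response_size <- tt2$size_value + 1
  tt2$response_color <- tt2$color_value + 1
  tt2$response_size[2] <- tt2$size_value[2] - 1     # adjusted smaller
  tt2$response_color[5] <- tt2$color_value[5] - 1   # adjusted greener
  bad <- incorrect_goal_relabel(tt2)
  expect_equal(bad$trial_id, tt2$trial_id[c(2, 5)])
  expect_equal(as.character(bad$actual_label),
               c("smaller_redder", "bigger_greener"))
})
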