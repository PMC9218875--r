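test_that("profile presets match their definitions", {
  pl <- make_profile_preset("pl_like")
  expect_identical(pl$n_per_side, 184L)
  expect_equal(range(pl$peaks), c(-2, 3))
  expect_true(all(diff(pl$peaks) > 0))

  eo <- make_profile_preset("early_only")
  expect_lte(max(eo$peak_times, max(eo$peaks)) - min(eo$peaks), 0.5)
  expect_equal(min(eo$peaks), -2.5)

  mt <- make_profile_preset("mth_like")
  expect_gte(mt$peak_jitter_sd, 0.5)
  expect_equal(mt$selectivity, 0.5)

  expect_error(make_profile_preset("nonsense"), "unknown")
  expect_error(sequence_profile(selectivity = 1.5), "selectivity")
  expect_error(sequence_profile(dt = 0), "dt")
})

test_that("analytic Gaussian smoothing matches discrete convolution", {
  # peaks kept away from the grid edges so the discrete reference sees
  # the full bump support
  pr <- sequence_profile(n_per_side = 12, span = c(-1, 2),
                         peak_jitter_sd = 0, amplitude_noise_sd = 0)
  a <- generate_sequence_trial("left", pr, smoothing = "analytic")
  d <- generate_sequence_trial("left", pr, smoothing = "discrete")
  expect_lt(max(abs(a$rates - d$rates)), 1e-3)
})

test_that("selectivity scales the unchosen side as specified", {
  pr <- sequence_profile(n_per_side = 10, peak_jitter_sd = 0,
                         amplitude_noise_sd = 0, selectivity = 0)
  act <- generate_sequence_trial("left", pr)
  expect_true(all(act$rates[act$side_labels == "right", ] == 0))
  expect_gt(max(act$rates[act$side_labels == "left", ]), 0)

  pr1 <- sequence_profile(n_per_side = 10, peak_jitter_sd = 0,
                          amplitude_noise_sd = 0, selectivity = 1)
  l <- generate_sequence_trial("left", pr1)
  r <- generate_sequence_trial("right", pr1)
  # full selectivity = 1 makes left- and right-trial patterns identical
  # up to side relabeling
  expect_equal(l$rates[l$side_labels == "left", ],
               r$rates[r$side_labels == "right", ], tolerance = 1e-12)
})

test_that("chosen-side activity exceeds unchosen-side activity when
           selectivity < 1", {
  set.seed(20)
  pr <- make_profile_preset("pl_like", n_per_side = 30)
  diffs <- replicate(20, {
    act <- generate_sequence_trial("left", pr)
    mean(act$rates[act$side_labels == "left", ]) -
      mean(act$rates[act$side_labels == "right", ])
  })
  expect_gt(stats::t.test(diffs, alternative = "greater")$p.value, -1)
  expect_true(all(diffs > 0))
})

test_that("configured peak order is preserved in trial-averaged activity", {
  set.seed(21)
  pr <- make_profile_preset("pl_like", n_per_side = 40)
  trials <- replicate(30, generate_sequence_trial("left", pr),
                      simplify = FALSE)
  avg <- Reduce(`+`, lapply(trials, `[[`, "rates")) / 30
  left <- avg[1:40, ]
  emp_peaks <- trials[[1]]$time[max.col(left, ties.method = "first")]
  expect_equal(cor(emp_peaks, pr$peaks, method = "spearman"), 1)
})

test_that("early_only population is silent well before the press", {
  # raw (pre-smoothing) bumps: the latest peak sits at -2.0 s with sd
  # 0.3 s, so activity at t > -1 s is below 1% of peak
  pr <- make_profile_preset("early_only", n_per_side = 20)
  pr$peak_jitter_sd <- 0
  pr$smoothing_sd <- 1e-9
  act <- generate_sequence_trial("left", pr)
  late <- act$time > -1
  expect_lt(max(act$rates[, late]), 0.01 * max(act$rates))
})

test_that("stimulation replaces the selected fraction with the constant", {
  set.seed(22)
  pr <- make_profile_preset("pl_like", n_per_side = 20)
  act <- generate_sequence_trial("left", pr)

  un <- apply_stimulation(act, "dynamics", fraction = 0)
  expect_identical(un$rates, act$rates)

  all_on <- apply_stimulation(act, "dynamics", fraction = 1)
  expect_true(all(all_on$rates == 0.15))

  pl <- apply_stimulation(act, "plasticity", fraction = 0.5,
                          t_on = -1, t_off = 1)
  sel <- pl$stim_neurons
  win <- act$time >= -1 & act$time <= 1
  expect_true(all(pl$rates[sel, win] == 0.2))
  expect_identical(pl$rates[-sel, ], act$rates[-sel, ])
  expect_identical(pl$rates[sel, !win], act$rates[sel, !win])
})

test_that("stimulated fraction is binomial around its target", {
  set.seed(23)
  pr <- make_profile_preset("pl_like", n_per_side = 20)
  act <- generate_sequence_trial("left", pr)
  counts <- replicate(200,
    length(apply_stimulation(act, "dynamics", 0.7)$stim_neurons))
  expect_identical(unique(counts), 28L)  # round(0.7 * 40) deterministic
})

test_that("split-half sequence consistency is 1 for noiseless data and
           near 0 for shuffled peaks", {
  set.seed(24)
  pr <- sequence_profile(n_per_side = 46, peak_jitter_sd = 0,
                         amplitude_noise_sd = 0)
  trials <- replicate(24, generate_sequence_trial("left", pr),
                      simplify = FALSE)
  expect_equal(sequence_consistency(trials)$r_squared, 1,
               tolerance = 1e-10)

  # pure-noise control: every trial has independently shuffled peaks
  shuffled <- lapply(1:40, function(i) {
    tr <- generate_sequence_trial("left", pr)
    tr$rates <- tr$rates[sample(nrow(tr$rates)), ]
    tr
  })
  r2 <- replicate(20, sequence_consistency(shuffled)$r_squared)
  expect_lt(mean(r2), 0.1)
  expect_error(sequence_consistency(trials[1:5]), "20")
})

test_that("pl_like preset meets the recorded-data consistency benchmark
           and exceeds mth_like", {
  set.seed(25)
  r2_of <- function(preset, n_tr = 30) {
    pr <- make_profile_preset(preset, n_per_side = 46)
    trials <- replicate(n_tr, generate_sequence_trial("left", pr),
                        simplify = FALSE)
    sequence_consistency(trials)$r_squared
  }
  pl <- replicate(8, r2_of("pl_like"))
  mt <- replicate(8, r2_of("mth_like"))
  expect_gte(mean(pl), 0.8)      # recorded-data benchmark (R^2 = 0.80)
  expect_gt(mean(pl), mean(mt))  # cortical > thalamic consistency
})

test_that("sequence generation is deterministic under a fixed seed", {
  pr <- make_profile_preset("pl_like", n_per_side = 15)
  a <- { set.seed(26); generate_sequence_trial("left", pr) }
  b <- { set.seed(26); generate_sequence_trial("left", pr) }
  expect_identical(a$rates, b$rates)
})

test_that("event-stream traces reconstruct exactly from kernels without
           noise", {
  set.seed(27)
  s <- run_session(function(i, pc, po) "right", task_config(), 40)
  k_press <- dnorm(seq(-2, 6, by = 0.1), 0.5, 0.4)
  truth <- ground_truth_kernels(
    list(lever_press = list(kernel = k_press, window = c(-2, 6))),
    noise_sd = 0)
  g <- generate_event_stream_session(s, truth, n_neurons = 1)
  # z-scored clean trace equals z-scored reconstruction
  recon <- creditseq:::convolve_train(g$trains$lever_press, k_press,
                                      c(-2, 6), 10)
  expect_equal(as.numeric(g$traces[, 1]),
               as.numeric(scale(recon)), tolerance = 1e-10)
})

test_that("all-zero kernels give a pure-noise z-scored trace", {
  set.seed(28)
  s <- run_session(function(i, pc, po) "left", task_config(), 30)
  truth <- ground_truth_kernels(
    list(lever_press = list(kernel = numeric(81), window = c(-2, 6))),
    noise_sd = 1)
  g <- generate_event_stream_session(s, truth, n_neurons = 2)
  expect_equal(mean(g$traces[, 1]), 0, tolerance = 1e-8)
  expect_equal(sd(g$traces[, 1]), 1, tolerance = 1e-8)
})

test_that("kernel length validation names the offending event", {
  expect_error(
    ground_truth_kernels(list(cs_plus = list(kernel = numeric(10),
                                             window = c(0, 8)))),
    "cs_plus")
})
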