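test_that("sequence-type weights are inverse triplet frequencies", {
  labs <- c("L", "L", "L", "L", "R", "L")
  w <- sequence_type_weights(labs)
  expect_true(is.na(w[1]) && is.na(w[6]))
  # triplets: LLL, LLL, LLR, LRL -> counts LLL:2, LLR:1, LRL:1
  expect_equal(w[2], 0.5)
  expect_equal(w[3], 0.5)
  expect_equal(w[4], 1)
  expect_equal(w[5], 1)

  # all-identical labels: single type, uniform weights
  w1 <- sequence_type_weights(rep("L", 10))
  expect_true(all(w1[2:9] == w1[2]))
})

test_that("decoder is perfect on separable features and at chance on
           shuffled labels", {
  set.seed(70)
  n <- 120
  labs <- sample(c("ipsi", "contra"), n, replace = TRUE)
  X <- matrix(rnorm(n * 12, sd = 0.1), n, 12) +
    outer(ifelse(labs == "ipsi", 1, -1), rep(1, 12))
  spec <- decoder_spec(ensemble_size = 5, n_resamples = 20)
  expect_equal(decode_labels(X, labs, spec)$accuracy, 1)

  shuf <- sample(labs)
  acc <- decode_labels(matrix(rnorm(n * 12), n, 12), shuf, spec)$accuracy
  expect_equal(acc, 0.5, tolerance = 0.1)
  expect_error(decode_labels(X[, 1:3], labs, spec), "neurons")
})

test_that("accuracy is invariant to relabeling plus feature sign flip", {
  set.seed(71)
  n <- 100
  labs <- sample(c("a", "b"), n, replace = TRUE)
  X <- matrix(rnorm(n * 10), n, 10) +
    0.8 * outer(ifelse(labs == "a", 1, -1), rep(1, 10))
  spec <- decoder_spec(ensemble_size = 10, n_resamples = 10)
  a1 <- { set.seed(5); decode_labels(X, labs, spec)$accuracy }
  flip <- ifelse(labs == "a", "b", "a")
  a2 <- { set.seed(5); decode_labels(-X, flip, spec)$accuracy }
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("reweighting removes previous-choice leakage", {
  # activity encodes only the PREVIOUS choice; with sticky choices an
  # unweighted decoder scores above chance on the current label, the
  # weighted decoder does not
  set.seed(72)
  n <- 400
  labs <- character(n); labs[1] <- "L"
  for (i in 2:n) labs[i] <- if (runif(1) < 0.8) labs[i - 1] else
    setdiff(c("L", "R"), labs[i - 1])
  prev <- c("L", labs[-n])
  X <- matrix(rnorm(n * 10, sd = 0.3), n, 10) +
    outer(ifelse(prev == "L", 1, -1), rep(1, 10))
  spec <- decoder_spec(ensemble_size = 10, n_resamples = 15)
  unw <- decode_labels(X, labs, spec, weights = rep(1, n))$accuracy
  wts <- decode_labels(X, labs, spec)$accuracy
  expect_gt(unw, 0.6)
  expect_lt(abs(wts - 0.5), abs(unw - 0.5))
})

test_that("time warp is the identity for median-length trials and maps
           epoch midpoints linearly", {
  rate <- 10
  time <- seq(0, 120, by = 1 / rate)
  traces <- cbind(sin(time / 3), time / 50)
  # trials with identical epoch durations: warp must be the identity
  anchors <- data.frame(nose_poke = c(10, 30, 50),
                        lever_press = c(11.5, 31.5, 51.5),
                        next_nose_poke = c(20, 40, 60))
  w <- time_warp_trials(traces, time, anchors, rate)
  expect_identical(w$dropped, integer(0))
  expect_equal(unname(w$median_epochs), c(1.5, 8.5))
  for (tr in 1:3) {
    orig_idx <- which(time >= anchors$nose_poke[tr] - 2 - 1e-9 &
                        time <= anchors$next_nose_poke[tr] + 3 + 1e-9)
    expect_equal(w$warped[tr, , 1],
                 traces[orig_idx, 1], tolerance = 1e-9)
  }

  # heterogeneous epoch ii: the linear map sends the epoch midpoint of a
  # 1.5 s nose-poke-to-press interval to the midpoint of the 1.0 s median
  anchors2 <- data.frame(nose_poke = c(10, 30, 50),
                         lever_press = c(11.5, 31, 50.5),
                         next_nose_poke = c(20, 40, 60))
  ramp <- cbind(time)          # trace equal to time itself
  w2 <- time_warp_trials(ramp, time, anchors2, rate)
  m2 <- unname(w2$median_epochs["ii"])
  expect_equal(m2, 1)
  # adjusted time 0.5 (half the median epoch) on trial 1 should read the
  # original trace at nose_poke + 0.5 / 1 * 1.5 = 10.75
  col <- which.min(abs(w2$adj_time - 0.5))
  expect_equal(w2$warped[1, col, 1], 10.75, tolerance = 1e-6)

  # piecewise-linear input stays piecewise linear (interpolation)
  expect_true(all(abs(diff(diff(w2$warped[1, w2$adj_time > 0.05 &
                                             w2$adj_time < 0.95, 1]))) <
                    1e-6))
})

test_that("non-monotone trials are dropped and reported", {
  time <- seq(0, 100, by = 0.1)
  traces <- matrix(rnorm(length(time)), ncol = 1)
  anchors <- data.frame(nose_poke = c(10, 30), lever_press = c(9, 31),
                        next_nose_poke = c(20, 40))
  w <- time_warp_trials(traces, time, anchors, 10)
  expect_identical(w$dropped, 1L)
  expect_identical(w$kept, 2L)
})

test_that("timecourse decoding finds the label where it is encoded and
           chance elsewhere", {
  set.seed(73)
  rate <- 10
  n_tr <- 90
  trial_len <- 12
  time <- seq(0, n_tr * trial_len, by = 1 / rate)
  labs <- sample(c("L", "R"), n_tr, replace = TRUE)
  np <- (seq_len(n_tr) - 1) * trial_len + 3
  anchors <- data.frame(nose_poke = np, lever_press = np + 1.5,
                        next_nose_poke = np + trial_len)
  n_neu <- 10
  traces <- matrix(rnorm(length(time) * n_neu, sd = 0.25), ncol = n_neu)
  # label signal present only from press to press + 2 s
  for (tr in seq_len(n_tr)) {
    idx <- time >= anchors$lever_press[tr] &
      time <= anchors$lever_press[tr] + 2
    traces[idx, ] <- traces[idx, ] + ifelse(labs[tr] == "L", 1, -1)
  }
  w <- time_warp_trials(traces, time, anchors, rate)
  spec <- decoder_spec(ensemble_size = 10, n_resamples = 8)
  tc <- timecourse_decoding(w, labs, lag = 0, spec = spec)
  m2 <- unname(w$median_epochs["ii"])
  in_sig <- tc$bin_mid > m2 + 0.3 & tc$bin_mid < m2 + 1.7
  pre <- tc$bin_mid < -0.5
  expect_gt(mean(tc$accuracy[in_sig]), 0.9)
  expect_lt(mean(tc$accuracy[pre]), 0.65)

  # a label two trials back is never decodable from this activity
  tc2 <- timecourse_decoding(w, labs, lag = -2, spec = spec)
  expect_lt(mean(tc2$accuracy), 0.6)
})

test_that("warping cannot exceed the per-trial trace extremes", {
  set.seed(74)
  time <- seq(0, 100, by = 0.1)
  traces <- matrix(rnorm(length(time)), ncol = 1)
  anchors <- data.frame(nose_poke = c(10, 30), lever_press = c(11, 32),
                        next_nose_poke = c(20, 40))
  w <- time_warp_trials(traces, time, anchors, 10)
  for (tr in 1:2) {
    lo <- anchors$nose_poke[tr] - 2; hi <- anchors$next_nose_poke[tr] + 3
    rng <- range(traces[time >= lo - 0.11 & time <= hi + 0.11, 1])
    expect_gte(min(w$warped[tr, , 1]), rng[1] - 1e-9)
    expect_lte(max(w$warped[tr, , 1]), rng[2] + 1e-9)
  }
})

test_that("consistent cortical-like sequences decode choice better than
           thalamic-like ones", {
  set.seed(75)
  session_features <- function(preset, n_tr = 80) {
    pr <- make_profile_preset(preset, n_per_side = 12)
    labs <- sample(c("left", "right"), n_tr, replace = TRUE)
    trials <- lapply(labs, function(sd) generate_sequence_trial(sd, pr))
    list(X = activity_features(trials, c(-2, 3)), labs = labs)
  }
  spec <- decoder_spec(ensemble_size = 10, n_resamples = 15)
  acc <- sapply(1:3, function(k) {
    pl <- session_features("pl_like")
    mt <- session_features("mth_like")
    c(pl = decode_labels(pl$X, pl$labs, spec)$accuracy,
      mt = decode_labels(mt$X, mt$labs, spec)$accuracy)
  })
  expect_gt(mean(acc["pl", ]), mean(acc["mt", ]))
  expect_gt(mean(acc["pl", ]), 0.6)
})
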