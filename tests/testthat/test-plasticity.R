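pp <- plasticity_params()

test_that("value readout is a side-split weighted sum", {
  w <- c(2, 0, 1, 3); f <- c(0.5, 1, 0.2, 0)
  side <- c("left", "left", "right", "right")
  v <- compute_value(w, f, side)
  expect_equal(v$V_L, 1)
  expect_equal(v$V_R, 0.2)
  expect_equal(v$V, 1.2)
  v0 <- compute_value(rep(0, 4), f, side)
  expect_equal(v0$V, 0)
  v2 <- compute_value(2 * w, f, side)
  expect_equal(v2$V, 2 * v$V)
  expect_error(compute_value(w, f[1:3], side), "aligned")
})

test_that("RPE closed forms hold", {
  expect_equal(compute_rpe(0, 0, 0, pp), 0)
  # constant unit value, no reward: delta = (gamma - 1) / Delta
  expect_equal(compute_rpe(1, 1, 0, pp), (exp(-0.01 / 0.7) - 1) / 0.01)
  expect_equal(compute_rpe(1, 1, 0, pp), -1.418416, tolerance = 1e-6)
  expect_equal(compute_rpe(0, 0, 2.5, pp), 2.5)
})

test_that("eligibility recursion matches its closed form", {
  e <- update_eligibility(0, 0, pp)
  expect_identical(e, 0)
  e1 <- update_eligibility(0, 1, pp)
  expect_equal(e1, 0.01)
  e2 <- update_eligibility(e1, 0, pp)
  expect_equal(e2, 0.01 * exp(-0.0125), tolerance = 1e-12)
  # pure decay over k silent steps
  ek <- Reduce(function(e, .) update_eligibility(e, 0, pp), 1:50, 0.3)
  expect_equal(ek, 0.3 * exp(-50 * 0.01 / 0.8), tolerance = 1e-12)
})

test_that("weight updates follow forward Euler with the Dale clip", {
  up <- update_weights(0.1, 10, 1, alpha = 0.009, dt = 0.01)
  expect_equal(up$w_hat, 0.1009)
  up0 <- update_weights(0.1, 0, 1, 0.009, 0.01)
  expect_equal(up0$w_hat, 0.1)
  neg <- update_weights(-0.05, 0, 1, 0.009, 0.01)
  expect_identical(neg$w, 0)
  expect_equal(neg$w_hat, -0.05)
})

test_that("reward kernel has the Gaussian peak and hard pre-peak cutoff", {
  tg <- seq(-0.5, 3, by = 0.001)
  r <- reward_kernel(1, tg, mu_r = 0.7)
  expect_equal(max(r), 1 / (0.3 * sqrt(2 * pi)), tolerance = 1e-4)
  expect_equal(tg[which.max(r)], 0.7, tolerance = 1e-3)
  expect_true(all(r[tg < 0.5] == 0))
  expect_gt(r[which.min(abs(tg - 0.5001))], 0)
  expect_identical(reward_kernel(0, tg, 0.7), rep(0, length(tg)))
})

test_that("action selection has the closed-form stay bias and symmetry", {
  set.seed(30)
  peaks <- rep(seq(-2, 3, length.out = 20), 2)
  side <- rep(c("left", "right"), each = 20)
  w <- rep(0.01, 40)
  # equal weights, no previous choice: P(left) = 0.5 in expectation
  ps <- replicate(3000, {
    a <- select_action(w, peaks, side, "none", pp)
    c(a$p_left, a$choice == "left")
  })
  expect_equal(mean(ps[2, ]), 0.5, tolerance = 3 * 0.5 / sqrt(3000))

  # d_left = d_right exactly: stay term alone gives 1/(1+exp(-0.15))
  pp0 <- plasticity_params(probe_sd = 0)
  a <- select_action(w, peaks, side, "left", pp0)
  expect_equal(a$d_left, a$d_right)
  expect_equal(a$p_left, 1 / (1 + exp(-0.15)), tolerance = 1e-12)
  expect_equal(1 / (1 + exp(-0.15)), 0.537, tolerance = 1e-3)

  # infinite gain saturates the softmax
  w_big <- w; w_big[side == "left"] <- 0.02
  pbig <- plasticity_params(probe_sd = 0, beta_value = 1e9)
  abig <- select_action(w_big, peaks, side, "none", pbig)
  expect_equal(abig$p_left, 1)
})

test_that("compiled trial integration equals the pure-R reference", {
  set.seed(31)
  pr <- make_profile_preset("pl_like", n_per_side = 15)
  sp <- creditseq:::smoothed_bump_pars(pr)
  n <- 30
  mu <- rep(pr$peaks, 2) + rnorm(n, 0, 0.05)
  amp <- runif(n, 0.5, 1.5)
  w0 <- runif(n, -0.01, 0.02)
  tg <- seq(-2.6, 3, by = 0.01)
  r <- reward_kernel(1, tg, 0.8)
  for (floor in c(TRUE, FALSE)) {
    a <- creditseq:::plasticity_trial_cpp(mu, amp, sp$sd, w0, 3:12, 0.2,
                                          -2.6, 1.4, -2.6, 3, 0.01, r,
                                          0.009, 0.7, 0.8, 0.01, floor)
    b <- creditseq:::plasticity_trial_ref(mu, amp, sp$sd, w0, 3:12, 0.2,
                                          -2.6, 1.4, -2.6, 3, 0.01, r,
                                          pp, floor)
    expect_equal(a$w_hat, b$w_hat, tolerance = 1e-9)
    expect_equal(a$value, b$value, tolerance = 1e-9)
    expect_equal(a$rpe, b$rpe, tolerance = 1e-9)
  }
})

test_that("RPE integrates to the delivered reward mass on a surprise
           reward and to ~0 once the trial is fully learned", {
  set.seed(32)
  pr <- make_profile_preset("pl_like", n_per_side = 20)
  sp <- creditseq:::smoothed_bump_pars(pr)
  n <- 40
  mu <- rep(pr$peaks, 2)
  amp <- rep(pr$peak_amplitude * sp$amp, n)
  tg <- seq(-2.5, 3, by = 0.01)
  r <- reward_kernel(1, tg, 0.7)
  # zero weights and frozen learning: delta reduces to r, so the
  # integral is exactly the delivered reward mass
  res <- creditseq:::plasticity_trial_cpp(mu, amp, sp$sd, numeric(n),
                                          integer(0), 0, 0, 0, -2.5, 3,
                                          0.01, r, 0, 0.7, 0.8, 0.01,
                                          TRUE)
  expect_equal(sum(res$rpe) * 0.01, sum(r) * 0.01, tolerance = 1e-10)

  # train to convergence on a deterministic rewarded trial, then the
  # within-trial RPE largely cancels (reward predicted away)
  w <- numeric(n)
  for (i in 1:300) {
    out <- creditseq:::plasticity_trial_cpp(mu, amp, sp$sd, w,
                                            integer(0), 0, 0, 0, -2.5, 3,
                                            0.01, r, 0.009, 0.7, 0.8,
                                            0.01, TRUE)
    w <- out$w_hat
  }
  final <- creditseq:::plasticity_trial_cpp(mu, amp, sp$sd, w,
                                            integer(0), 0, 0, 0, -2.5, 3,
                                            0.01, r, 0.009, 0.7, 0.8,
                                            0.01, TRUE)
  naive <- sum(r) * 0.01
  learned <- sum(final$rpe) * 0.01
  expect_lt(abs(learned), 0.25 * naive)
})

test_that("plasticity session obeys its structural invariants", {
  set.seed(33)
  run <- run_plasticity_session(make_profile_preset("pl_like",
                                                    n_per_side = 46),
                                n_trials = 300)
  expect_true(all(run$w >= 0))
  s <- run$session
  expect_true(all(s$choice %in% c("left", "right")))
  expect_identical(nrow(s), 300L)
  # alpha = 0: weights never move, choices reduce to stay-biased flips
  set.seed(34)
  frozen <- run_plasticity_session(make_profile_preset("pl_like",
                                                       n_per_side = 46),
                                   params = plasticity_params(alpha = 0),
                                   n_trials = 400)
  expect_true(all(frozen$w == 0))
  expect_equal(mean(frozen$session$outcome), 0.4, tolerance = 0.08)
})

test_that("plasticity sessions are reproducible under a fixed seed", {
  pr <- make_profile_preset("pl_like", n_per_side = 20)
  a <- { set.seed(35); run_plasticity_session(pr, n_trials = 60) }
  b <- { set.seed(35); run_plasticity_session(pr, n_trials = 60) }
  expect_identical(a$w_hat, b$w_hat)
  expect_identical(a$session$choice, b$session$choice)
})

test_that("learned model stays more after rewards than omissions and the
           gap shrinks for the early-only control", {
  set.seed(36)
  run <- run_plasticity_session(make_profile_preset("pl_like",
                                                    n_per_side = 92),
                                n_trials = 1200)
  sp <- stay_probability(run$session)
  gap_pl <- sp$stay[sp$prev_outcome == 1] - sp$stay[sp$prev_outcome == 0]
  expect_gt(gap_pl, 0)

  set.seed(37)
  eo <- run_plasticity_session(make_profile_preset("early_only",
                                                   n_per_side = 92),
                               params = plasticity_params(alpha = 0.003,
                                                          beta_value = 1000),
                               n_trials = 1200)
  spe <- stay_probability(eo$session)
  gap_eo <- spe$stay[spe$prev_outcome == 1] -
    spe$stay[spe$prev_outcome == 0]
  expect_gt(gap_pl, gap_eo)
})
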