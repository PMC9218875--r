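# small session + design shared across tests
make_encoding_fixture <- function(n_trials = 60, seed = 60,
                                  events = c("nose_poke", "ipsi_press",
                                             "cs_plus")) {
  set.seed(seed)
  s <- run_session(function(i, pc, po)
    if (runif(1) < 0.5) "left" else "right",
    task_config(), n_trials)
  trains <- event_trains_from_session(s, events = events)
  bases <- lapply(trains$windows, build_spline_basis)
  design <- build_design_matrix(trains$trains, bases)
  list(session = s, trains = trains, bases = bases, design = design)
}

test_that("spline basis has the canonical 81 x 25 shape and partition of
           unity", {
  b <- build_spline_basis(c(-2, 6), 25, 10)
  expect_identical(dim(b$S), c(81L, 25L))
  expect_equal(rowSums(b$S), rep(1, 81), tolerance = 1e-10)
  expect_true(all(b$S >= 0))
  b2 <- build_spline_basis(c(0, 8), 25, 10)
  expect_identical(nrow(b2$S), 81L)
  expect_error(build_spline_basis(c(0, 0.5), 25, 10), "invalid")
})

test_that("any constant is reproducible by the basis to 1e-8", {
  b <- build_spline_basis()
  target <- rep(3.7, 81)
  fit <- lm.fit(b$S, target)
  expect_lt(max(abs(fit$residuals)), 1e-8)
})

test_that("design matrix equals shifted basis copies for isolated and
           overlapping events", {
  T_len <- 400
  b <- build_spline_basis(c(-2, 6), 25, 10)
  tr0 <- numeric(T_len)
  d0 <- build_design_matrix(list(ev = tr0), b)
  expect_true(all(d0$X == 0))

  tr1 <- numeric(T_len); tr1[100] <- 1
  d1 <- build_design_matrix(list(ev = tr1), b)
  # column j is S_j placed with sample 1 at t0 - 20 (window start -2 s)
  expect_equal(d1$X[(100 - 20):(100 + 60), 3], b$S[, 3],
               tolerance = 1e-12)
  expect_true(all(d1$X[1:70, ] == 0))

  tr2 <- numeric(T_len); tr2[c(100, 130)] <- 1
  d2 <- build_design_matrix(list(ev = tr2), b)
  tr2b <- numeric(T_len); tr2b[130] <- 1
  d2b <- build_design_matrix(list(ev = tr2b), b)
  expect_equal(d2$X, d1$X + d2b$X, tolerance = 1e-12)
  expect_error(build_design_matrix(list(a = tr1, b = tr1[1:10]), b),
               "equal length")
})

test_that("noiseless kernels are recovered with correlation >= 0.99", {
  fx <- make_encoding_fixture()
  k_true <- list(
    nose_poke = dnorm(seq(-2, 6, by = 0.1), 0, 0.5),
    ipsi_press = -0.5 * dnorm(seq(-2, 6, by = 0.1), 1, 0.8),
    cs_plus = dnorm(seq(0, 8, by = 0.1), 1.5, 0.6))
  truth <- ground_truth_kernels(
    list(nose_poke = list(kernel = k_true$nose_poke, window = c(-2, 6)),
         ipsi_press = list(kernel = k_true$ipsi_press, window = c(-2, 6)),
         cs_plus = list(kernel = k_true$cs_plus, window = c(0, 8))),
    noise_sd = 0)
  g <- generate_event_stream_session(fx$session, truth, n_neurons = 1)
  fit <- fit_kernel_model(g$traces[, 1], fx$design, penalty = "none")
  ks <- kernel_set(fit, fx$bases)
  for (ev in names(k_true))
    expect_gte(cor(ks[[ev]], k_true[[ev]]), 0.99)
})

test_that("lasso with huge penalty shrinks everything to the intercept", {
  fx <- make_encoding_fixture(n_trials = 40)
  set.seed(61)
  y <- rnorm(nrow(fx$design$X))
  beta <- glmnet::glmnet(fx$design$X, y, lambda = 1e6,
                         standardize = FALSE)
  expect_equal(sum(abs(as.numeric(beta$beta))), 0)
})

test_that("lasso on pure noise is sparse at the CV-chosen penalty", {
  fx <- make_encoding_fixture(n_trials = 40)
  set.seed(62)
  y <- rnorm(nrow(fx$design$X))
  fit <- fit_kernel_model(y, fx$design, penalty = "lasso_cv")
  expect_gte(mean(fit$beta == 0), 0.9)
})

test_that("press-only neurons are flagged for press but not for CS, and
           the multi-peak artifact stays in the raw averages", {
  fx <- make_encoding_fixture(n_trials = 80, seed = 63)
  kp <- dnorm(seq(-2, 6, by = 0.1), 0.5, 0.4)
  truth <- ground_truth_kernels(
    list(ipsi_press = list(kernel = kp, window = c(-2, 6))),
    noise_sd = 0.3)
  set.seed(64)
  g <- generate_event_stream_session(fx$session, truth, n_neurons = 1)
  y <- g$traces[, 1]
  sig_press <- nested_event_significance(y, fx$design, "ipsi_press",
                                         n_shuffle = 200)
  sig_cs <- nested_event_significance(y, fx$design, "cs_plus",
                                      n_shuffle = 200)
  expect_true(sig_press$significant)
  expect_false(sig_cs$significant)

  # fitted CS kernel is near zero even though the event-locked average
  # of a press-only neuron is not (events are temporally correlated)
  fit <- fit_kernel_model(y, fx$design, penalty = "none")
  ks <- kernel_set(fit, fx$bases)
  expect_lt(max(abs(ks$cs_plus)) / max(abs(ks$ipsi_press)), 0.35)
  cs_train <- fx$trains$trains$cs_plus
  eta <- sapply(which(cs_train == 1), function(i)
    if (i + 20 <= length(y)) mean(y[i:(i + 20)]) else NA)
  expect_gt(abs(mean(eta, na.rm = TRUE)), 0.05)
})

test_that("circular-shift null has calibrated type-I error at p = 0.01", {
  fx <- make_encoding_fixture(n_trials = 50, seed = 65)
  set.seed(66)
  n_neu <- 60
  p_vals <- replicate(n_neu, {
    y <- as.numeric(stats::filter(rnorm(nrow(fx$design$X)), 0.6,
                                  method = "recursive"))
    nested_event_significance(y, fx$design, "ipsi_press",
                              n_shuffle = 150, n_events = 1)$p_value
  })
  # false-positive rate at alpha = 0.05 within binomial CI of nominal
  fp <- mean(p_vals < 0.05)
  expect_lte(fp, 0.05 + 3 * sqrt(0.05 * 0.95 / n_neu))
  # p-values roughly uniform: mean near 0.5
  expect_equal(mean(p_vals), 0.5, tolerance = 0.15)
})

test_that("choice and outcome selectivity are read from the right
           reduced models", {
  set.seed(67)
  s <- run_session(function(i, pc, po)
    if (runif(1) < 0.5) "left" else "right", task_config(), 80)
  trains <- event_trains_from_session(s,
                                      events = selectivity_event_set())
  bases <- lapply(trains$windows, build_spline_basis)
  design <- build_design_matrix(trains$trains, bases)
  T_len <- length(trains$trains[[1]])
  kp <- dnorm(seq(-2, 6, by = 0.1), 0.5, 0.4)

  # neuron responding to every press equally: captured by all_press
  both <- creditseq:::convolve_train(trains$trains$all_press, kp,
                                     c(-2, 6), 10)
  set.seed(68)
  y_both <- as.numeric(scale(both + rnorm(T_len, 0, 0.2)))
  expect_false(classify_selectivity(y_both, design, "choice",
                                    n_shuffle = 150)$significant)

  # neuron responding only to ipsilateral presses: choice-selective
  ipsi <- creditseq:::convolve_train(trains$trains$ipsi_press, kp,
                                     c(-2, 6), 10)
  y_ipsi <- as.numeric(scale(ipsi + rnorm(T_len, 0, 0.2)))
  expect_true(classify_selectivity(y_ipsi, design, "choice",
                                   n_shuffle = 150)$significant)

  # CS+-only neuron: outcome-selective, not choice-selective
  kcs <- dnorm(seq(0, 8, by = 0.1), 1, 0.5)
  cs <- creditseq:::convolve_train(trains$trains$cs_plus, kcs,
                                   c(0, 8), 10)
  y_cs <- as.numeric(scale(cs + rnorm(T_len, 0, 0.2)))
  expect_true(classify_selectivity(y_cs, design, "outcome",
                                   n_shuffle = 150)$significant)
  expect_false(classify_selectivity(y_cs, design, "choice",
                                    n_shuffle = 150)$significant)
})

test_that("orthogonal isolated events make OLS kernels equal
           event-triggered averages", {
  # single event type, events spaced far apart: the design is a disjoint
  # union of shifted bases, and the OLS kernel equals the ETA
  T_len <- 2000
  tr <- numeric(T_len); tr[seq(150, 1900, by = 150)] <- 1
  b <- build_spline_basis(c(-2, 6), 25, 10)
  d <- build_design_matrix(list(press = tr), b)
  k_true <- dnorm(seq(-2, 6, by = 0.1), 0.8, 0.5)
  y <- creditseq:::convolve_train(tr, k_true, c(-2, 6), 10)
  fit <- fit_kernel_model(y, d, penalty = "none")
  ker <- kernel_set(fit, b)$press
  eta <- rowMeans(sapply(which(tr == 1), function(i) y[(i - 20):(i + 60)]))
  expect_gt(cor(ker, eta), 0.999)
  expect_equal(max(abs(ker - eta)), 0, tolerance = 0.02 * max(abs(eta)))
})
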