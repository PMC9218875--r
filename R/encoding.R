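# Spline-basis event-kernel encoding model and shuffle-null nested
# significance tests for event modulation and choice/outcome selectivity.

ACTION_WINDOW <- c(-2, 6)
STIM_WINDOW <- c(0, 8)

#' Canonical event windows for the encoding model
#'
#' Action-locked events (nose poke, presses, reward consumption) use a
#' -2..6 s window; stimulus-locked events (levers out, CS tones) use
#' 0..8 s. Both are 81 samples at 10 Hz.
#'
#' @param events character vector of event names
#' @return named list of two-element windows
#' @export
event_windows <- function(events) {
  stim <- c("levers_out", "cs_plus", "cs_minus", "all_cs")
  out <- lapply(events, function(e)
    if (e %in% stim) STIM_WINDOW else ACTION_WINDOW)
  names(out) <- events
  out
}

#' Binary 10 Hz event trains from a behavioral session
#'
#' Lays the session's within-trial event times onto an absolute session
#' clock (2 s inter-trial intervals) and bins them into binary vectors.
#' `ipsi` fixes which lever counts as ipsilateral for the press events.
#'
#' Available event names: `nose_poke`, `levers_out`, `lever_press`,
#' `ipsi_press`, `contra_press`, `all_press`, `cs_plus`, `cs_minus`,
#' `all_cs`, `reward_consumption`.
#'
#' @param session a `cs_session` with event-time columns
#' @param events event names to build
#' @param rate sampling rate, Hz
#' @param ipsi `"right"` or `"left"`
#' @return list with `trains` (named binary vectors), `time`, `windows`,
#'   `press_abs` (absolute press times)
#' @export
event_trains_from_session <- function(session,
                                      events = c("nose_poke", "levers_out",
                                                 "ipsi_press",
                                                 "contra_press", "cs_plus",
                                                 "cs_minus",
                                                 "reward_consumption"),
                                      rate = 10, ipsi = "right") {
  need <- c("nose_poke", "levers_out", "lever_press", "cs")
  for (cl in need) {
    bad <- which(is.na(session[[cl]]) & session$choice != "none")
    if (length(bad))
      stopf("missing event time '%s' on trial %d", cl, bad[1])
  }
  abs_ev <- session_absolute_events(session)
  contra <- setdiff(c("left", "right"), ipsi)
  T_end <- max(abs_ev, na.rm = TRUE) + max(STIM_WINDOW)
  T_len <- ceiling(T_end * rate) + 1L
  time <- (seq_len(T_len) - 1) / rate
  done <- session$choice != "none"
  times_for <- function(ev) {
    switch(ev,
      nose_poke = abs_ev$nose_poke[done],
      levers_out = abs_ev$levers_out[done],
      lever_press = ,
      all_press = abs_ev$lever_press[done],
      ipsi_press = abs_ev$lever_press[done & session$choice == ipsi],
      contra_press = abs_ev$lever_press[done & session$choice == contra],
      cs_plus = abs_ev$cs[done & session$outcome == 1],
      cs_minus = abs_ev$cs[done & session$outcome == 0],
      all_cs = abs_ev$cs[done],
      reward_consumption = abs_ev$reward_consumption[done &
                                                     session$outcome == 1],
      stopf("unknown event '%s'", ev))
  }
  trains <- lapply(events, function(ev) {
    tr <- numeric(T_len)
    idx <- round(times_for(ev) * rate) + 1L
    idx <- idx[!is.na(idx) & idx >= 1 & idx <= T_len]
    tr[idx] <- 1
    tr
  })
  names(trains) <- events
  list(trains = trains, time = time, windows = event_windows(events),
       press_abs = abs_ev$lever_press, rate = rate)
}

#' The selectivity event set
#'
#' Event set used for choice/outcome-selectivity testing: press and CS
#' events are split into choice/outcome-blind regressors (`all_press`,
#' `all_cs`) plus informative ones (`ipsi_press`, `cs_plus`,
#' `reward_consumption`), so that dropping only the informative predictors
#' tests for selectivity rather than mere event modulation.
#'
#' @export
selectivity_event_set <- function() {
  c("nose_poke", "levers_out", "all_press", "ipsi_press", "all_cs",
    "cs_plus", "reward_consumption")
}

#' Cubic B-spline basis over a peri-event window
#'
#' Cubic B-splines with equally spaced interior knots, evaluated on the
#' inclusive sample grid of the window; normalized as a partition of unity.
#' The canonical windows (-2..6 s or 0..8 s at 10 Hz) yield an 81 x 25
#' basis matrix.
#'
#' @param window two-element window, seconds relative to the event
#' @param n_basis spline degrees of freedom (default 25)
#' @param rate sampling rate, Hz
#' @return a `cs_spline_basis`: list with matrix `S` (samples x n_basis),
#'   `grid`, `window`, `rate`
#' @export
build_spline_basis <- function(window = ACTION_WINDOW, n_basis = 25L,
                               rate = 10) {
  grid <- seq(window[1], window[2], by = 1 / rate)
  if (length(grid) < n_basis)
    stopf("invalid config: window too short for %d basis functions",
          n_basis)
  S <- splines::bs(seq_along(grid), df = n_basis, intercept = TRUE,
                   degree = 3)
  S <- unclass(S)[, , drop = FALSE]
  attributes(S)[setdiff(names(attributes(S)), "dim")] <- NULL
  structure(list(S = S, grid = grid, window = window, rate = rate,
                 n_basis = as.integer(n_basis)),
            class = "cs_spline_basis")
}

# shift a vector by `lag` samples (event at t contributes at t + lag),
# zero-padded
shift_vec <- function(x, lag) {
  n <- length(x)
  out <- numeric(n)
  if (lag >= 0) {
    if (lag < n) out[(1 + lag):n] <- x[1:(n - lag)]
  } else {
    if (-lag < n) out[1:(n + lag)] <- x[(1 - lag):n]
  }
  out
}

#' Design matrix from event trains and spline bases
#'
#' Convolves each binary event train with each spline basis function, so
#' that temporally delayed copies of the events can predict activity.
#' Kernel sample 1 is aligned to the window start (e.g. -2 s before an
#' action event). Columns are ordered by (event, basis function).
#'
#' @param trains named list of binary event trains (equal length)
#' @param bases a single [build_spline_basis()] applied to all events, or a
#'   named list of bases matching `trains`
#' @return list with `X` (time x (events x basis) matrix), `cols` (named
#'   list of column indices per event), `events`
#' @export
build_design_matrix <- function(trains, bases) {
  events <- names(trains)
  T_len <- unique(vapply(trains, length, 1L))
  if (length(T_len) != 1) stopf("event trains must have equal length")
  if (inherits(bases, "cs_spline_basis"))
    bases <- stats::setNames(rep(list(bases), length(events)), events)
  blocks <- vector("list", length(events))
  cols <- list(); at <- 0L
  for (k in seq_along(events)) {
    b <- bases[[events[k]]]
    off <- round(b$window[1] * b$rate)
    n_samp <- nrow(b$S)
    E <- vapply(seq_len(n_samp) - 1L,
                function(i) shift_vec(trains[[k]], off + i),
                numeric(T_len))
    blocks[[k]] <- E %*% b$S
    cols[[events[k]]] <- at + seq_len(ncol(b$S))
    at <- at + ncol(b$S)
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- unlist(lapply(events, function(e)
    paste0(e, "_b", seq_along(cols[[e]]))))
  list(X = X, cols = cols, events = events)
}

#' Fit the event-kernel encoding model to one trace
#'
#' Linear regression of a z-scored fluorescence trace on the spline-basis
#' design matrix. With `penalty = "lasso_cv"` the coefficients are lasso
#' regularized with the penalty chosen by 5-fold cross-validated MSE; with
#' `penalty = "none"` an ordinary least-squares fit is used (as in the
#' nested significance tests).
#'
#' @param trace numeric vector (z-scored fluorescence at the design rate)
#' @param design result of [build_design_matrix()]
#' @param penalty `"lasso_cv"` or `"none"`
#' @return a `cs_encoding_fit`: `beta` (named by design column),
#'   `intercept`, `lambda`, `cv_mse`, `design` metadata
#' @export
fit_kernel_model <- function(trace, design,
                             penalty = c("lasso_cv", "none")) {
  penalty <- match.arg(penalty)
  X <- design$X
  if (length(trace) != nrow(X))
    stopf("trace length (%d) does not match design (%d rows)",
          length(trace), nrow(X))
  if (penalty == "lasso_cv") {
    cvfit <- glmnet::cv.glmnet(X, trace, nfolds = 5, standardize = FALSE)
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))
    fit <- list(beta = beta[-1], intercept = beta[1],
                lambda = cvfit$lambda.min,
                cv_mse = min(cvfit$cvm), rank_deficient = FALSE)
  } else {
    ls <- lm.fit(cbind(1, X), trace)
    beta <- ls$coefficients
    rank_def <- anyNA(beta)
    if (rank_def) beta[is.na(beta)] <- 0
    fit <- list(beta = beta[-1], intercept = beta[1], lambda = 0,
                cv_mse = mean(ls$residuals^2), rank_deficient = rank_def)
  }
  names(fit$beta) <- colnames(X)
  fit$cols <- design$cols
  fit$events <- design$events
  fit$penalty <- penalty
  class(fit) <- "cs_encoding_fit"
  fit
}

#' Response kernels from an encoding fit
#'
#' The response kernel of event k is the spline reconstruction
#' `sum_j beta_jk S_j(t)` over that event's window: the neuron's linear
#' temporal response to the event, accounting for its response to all
#' other events.
#'
#' @param fit a `cs_encoding_fit`
#' @param bases the basis (or named list of bases) used for the design
#' @return named list of numeric kernels (81 samples each for the
#'   canonical windows)
#' @export
kernel_set <- function(fit, bases) {
  if (inherits(bases, "cs_spline_basis"))
    bases <- stats::setNames(rep(list(bases), length(fit$events)),
                             fit$events)
  out <- lapply(fit$events, function(e)
    as.numeric(bases[[e]]$S %*% fit$beta[fit$cols[[e]]]))
  names(out) <- fit$events
  out
}

# residual sums of squares of y (columns) under an orthonormal basis Q of
# the model column space
rss_under <- function(Q, Y) {
  Y <- as.matrix(Y)
  colSums(Y^2) - colSums(crossprod(Q, Y)^2)
}

circular_shift <- function(y, s) {
  n <- length(y)
  s <- ((s %% n) + n) %% n
  if (s == 0) y else c(y[(n - s + 1):n], y[1:(n - s)])
}

#' Nested significance of one or more events by circular-shift null
#'
#' Compares the full OLS encoding model with a reduced model lacking the
#' target event's predictors via an F-statistic, and calibrates it against
#' a null distribution obtained by circularly shifting the trace by random
#' integers (shifts smaller than one kernel length are excluded to avoid
#' near-identity nulls). The p-value is the fraction of shuffles whose F
#' meets or exceeds the observed one; significance applies a Bonferroni
#' correction over the number of events tested.
#'
#' @param trace numeric trace
#' @param design full design from [build_design_matrix()]
#' @param target_events event name(s) whose predictors the reduced model
#'   drops (several names are dropped jointly, as in the outcome test)
#' @param n_shuffle number of circular-shift shuffles (default 500)
#' @param alpha significance threshold before correction (default 0.01)
#' @param n_events Bonferroni divisor; defaults to the number of events in
#'   the design
#' @param min_shift smallest allowed shift magnitude, samples
#' @return list with `f_stat`, `p_value`, `significant`, `threshold`,
#'   `f_null`
#' @export
nested_event_significance <- function(trace, design, target_events,
                                      n_shuffle = 500, alpha = 0.01,
                                      n_events = NULL, min_shift = 81L) {
  if (n_shuffle < 100)
    warning("fewer than 100 shuffles limits p-value resolution")
  if (is.null(n_events)) n_events <- length(design$events)
  drop_cols <- unlist(design$cols[target_events])
  if (is.null(drop_cols) || !length(drop_cols))
    stopf("unknown target event(s)")
  Xf <- cbind(1, design$X)
  Xr <- cbind(1, design$X[, -drop_cols, drop = FALSE])
  Qf <- qr.Q(qr(Xf))
  Qr <- qr.Q(qr(Xr))
  T_len <- length(trace)
  p_full <- ncol(Xf)
  q <- length(drop_cols)
  f_of <- function(Y) {
    rf <- rss_under(Qf, Y); rr <- rss_under(Qr, Y)
    ((rr - rf) / q) / (rf / (T_len - p_full))
  }
  f_obs <- f_of(trace)
  smax <- T_len - min_shift
  if (smax <= min_shift) stopf("trace too short for circular-shift null")
  shifts <- sample(seq.int(min_shift, smax), n_shuffle, replace = TRUE)
  Ynull <- vapply(shifts, function(s) circular_shift(trace, s),
                  numeric(T_len))
  f_null <- f_of(Ynull)
  p <- mean(f_null >= f_obs)
  list(f_stat = f_obs, p_value = p,
       significant = p < alpha / n_events,
       threshold = alpha / n_events, f_null = f_null)
}

#' Choice or outcome selectivity of one neuron
#'
#' Uses the selectivity event set (which contains choice- and
#' outcome-blind regressors): a neuron is choice-selective when dropping
#' the `ipsi_press` predictors significantly degrades the model beyond the
#' circular-shift null, and outcome-selective when jointly dropping the
#' `cs_plus` and `reward_consumption` predictors does.
#'
#' @param trace numeric trace
#' @param design design built from [selectivity_event_set()] trains
#' @param kind `"choice"` or `"outcome"`
#' @inheritParams nested_event_significance
#' @return as [nested_event_significance()]
#' @export
classify_selectivity <- function(trace, design,
                                 kind = c("choice", "outcome"),
                                 n_shuffle = 500, alpha = 0.01) {
  kind <- match.arg(kind)
  target <- if (kind == "choice") "ipsi_press"
            else c("cs_plus", "reward_consumption")
  nested_event_significance(trace, design, target, n_shuffle = n_shuffle,
                            alpha = alpha,
                            n_events = length(design$events))
}
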