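# Biological TD-learning circuit: value from weighted input sequences,
# RPE via a delayed inhibitory pathway, eligibility-trace weight updates,
# and probabilistic action selection.

#' Parameters of the synaptic-plasticity TD circuit
#'
#' Defaults are the published circuit parameters: value is discounted on a
#' `tau_discount` = 0.7 s timescale; the delayed negative value copy
#' arrives `delta` = 0.01 s later (so the per-delay discount factor is
#' `gamma = exp(-delta / tau_discount)`); the synaptic eligibility trace
#' decays with `tau_e` = 0.8 s; weights learn at `alpha` = 0.009 per
#' (spikes/s); and choice is a softmax with gain `beta_value` = 7000 on
#' the probe-derived decision variables plus a `beta_stay` = 0.15 bias
#' toward the previous choice.
#'
#' The 50 ms probe drives the onset neurons of each side with
#' non-negative truncated-normal noise of mean `probe_mean` = 0.05 and sd
#' `probe_sd` = 0.0025 / dt (taken literally as printed, i.e. 0.25 at
#' dt = 0.01 s; exposed as a parameter). Reward arrives as a truncated
#' Gaussian of sd `reward_sigma` = 0.3 s whose peak time is uniform on
#' `reward_mu_range` = 0.2-1.2 s after the press. Updates run from
#' `t_start ~ N(-2.5, 0.2^2)` s to `t_end` = +3 s around the press, at
#' `dt` = 0.01 s.
#'
#' @param ... overrides of the defaults listed above
#' @return a `cs_plasticity_params` list
#' @export
plasticity_params <- function(...) {
  p <- list(tau_discount = 0.7, delta = 0.01, dt = 0.01, tau_e = 0.8,
            alpha = 0.009, beta_value = 7000, beta_stay = 0.15,
            probe_duration = 0.05, probe_mean = 0.05, probe_sd = NULL,
            n_probe_frac = 17 / 92, reward_mu_range = c(0.2, 1.2),
            reward_sigma = 0.3, t_start_mean = -2.5, t_start_sd = 0.2,
            t_end = 3, floor_each_step = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown)) stopf("unknown parameter(s): %s",
                             paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (is.null(p$probe_sd)) p$probe_sd <- 0.0025 / p$dt
  stopifnot(p$tau_discount > 0, p$tau_e > 0, p$dt > 0,
            p$delta >= p$dt)
  p$gamma <- exp(-p$delta / p$tau_discount)
  structure(p, class = "cs_plasticity_params")
}

#' Value readout from weighted input activity
#'
#' V_L and V_R are the weighted sums of the left- and right-preferring
#' basis-function activities; the total value is their sum (value is not
#' tied to a particular action because the chosen side's sequence
#' dominates the activity).
#'
#' @param weights per-neuron non-negative weights
#' @param activity per-neuron activity sample, aligned with `weights`
#' @param side_labels per-neuron `"left"`/`"right"` labels
#' @return list with `V_L`, `V_R`, `V`
#' @export
compute_value <- function(weights, activity, side_labels) {
  if (length(weights) != length(activity) ||
      length(weights) != length(side_labels))
    stopf("weights, activity and side_labels must be aligned by neuron")
  vl <- sum(weights[side_labels == "left"] *
              activity[side_labels == "left"])
  vr <- sum(weights[side_labels == "right"] *
              activity[side_labels == "right"])
  list(V_L = vl, V_R = vr, V = vl + vr)
}

#' Reward prediction error of the delayed-pathway circuit
#'
#' delta(t) = r(t) + (gamma V(t) - V(t - Delta)) / Delta with
#' gamma = exp(-Delta / tau): the dopamine population combines the reward
#' input, a fast discounted value signal and a delayed sign-inverted value
#' copy carried by the interneuron pathway.
#'
#' @param V_now value at time t
#' @param V_delayed value at time t - Delta (0 before the trial start)
#' @param r_now reward rate at time t
#' @param params a [plasticity_params()]
#' @return RPE per unit time
#' @export
compute_rpe <- function(V_now, V_delayed, r_now, params) {
  r_now + (params$gamma * V_now - V_delayed) / params$delta
}

#' Eligibility-trace update
#'
#' E <- exp(-dt / tau_e) E + f(t) dt, elementwise: an exponentially
#' decaying memory of recent presynaptic activity.
#'
#' @param E current eligibility vector
#' @param f_now activity vector at time t
#' @param params a [plasticity_params()]
#' @export
update_eligibility <- function(E, f_now, params) {
  exp(-params$dt / params$tau_e) * E + f_now * params$dt
}

#' Weight update with the non-negativity (Dale) constraint
#'
#' The unclipped accumulator follows dw_hat/dt = alpha delta E (forward
#' Euler); the exposed weights are w = max(0, w_hat). The accumulator is
#' retained so that learning can recover from excursions below zero.
#'
#' @param w_hat unclipped weight accumulator
#' @param delta RPE at time t
#' @param E eligibility vector
#' @param alpha learning rate
#' @param dt time step
#' @return list with `w_hat` and clipped `w`
#' @export
update_weights <- function(w_hat, delta, E, alpha, dt) {
  w_hat <- w_hat + alpha * delta * E * dt
  list(w_hat = w_hat, w = pmax(0, w_hat))
}

#' Truncated-Gaussian reward input
#'
#' On rewarded trials the reward input is a Gaussian density of sd
#' `sigma` centered at `mu_r` (drawn uniformly 0.2-1.2 s after the press),
#' set to zero earlier than 0.2 s before its peak so no reward response
#' precedes the press; on unrewarded trials it is identically zero.
#'
#' @param outcome 0 or 1
#' @param t_grid times at which to evaluate, seconds relative to press
#' @param mu_r peak reward time
#' @param sigma kernel width (default 0.3 s)
#' @return numeric reward-rate vector
#' @export
reward_kernel <- function(outcome, t_grid, mu_r, sigma = 0.3) {
  r <- outcome * dnorm(t_grid, mu_r, sigma)
  r[t_grid < mu_r - 0.2] <- 0
  r
}

# indices of the n_probe earliest-peaking neurons of each side
onset_neurons <- function(peak_times, side_labels, n_probe) {
  lapply(c(left = "left", right = "right"), function(s) {
    i <- which(side_labels == s)
    i[order(peak_times[i])][seq_len(min(n_probe, length(i)))]
  })
}

#' Probabilistic action selection by probing onset neurons
#'
#' A 50 ms probe of non-negative truncated-normal noise drives the
#' earliest-peaking (onset) neurons of each side; the decision variables
#' d_left and d_right are the probe-time averages of the weighted summed
#' activity, and the choice is a softmax of
#' `beta_value * d + beta_stay * I(previous choice)`.
#'
#' @param weights per-neuron weights (clipped, from the end of the
#'   previous trial)
#' @param peak_times,side_labels population layout
#' @param prev_choice previous trial's choice (`"none"` for the first)
#' @param params a [plasticity_params()]
#' @return list with `choice`, `d_left`, `d_right`, `p_left`
#' @export
select_action <- function(weights, peak_times, side_labels, prev_choice,
                          params) {
  n_side <- sum(side_labels == "left")
  n_probe <- max(1L, round(params$n_probe_frac * n_side))
  ons <- onset_neurons(peak_times, side_labels, n_probe)
  n_t <- max(1L, round(params$probe_duration / params$dt))
  dvar <- function(idx) {
    noise <- matrix(rtnorm0(length(idx) * n_t, params$probe_mean,
                            params$probe_sd), length(idx), n_t)
    mean(colSums(weights[idx] * noise))
  }
  d_left <- dvar(ons$left); d_right <- dvar(ons$right)
  i_l <- as.numeric(identical(prev_choice, "left"))
  i_r <- as.numeric(identical(prev_choice, "right"))
  z <- params$beta_value * (d_left - d_right) +
    params$beta_stay * (i_l - i_r)
  p_left <- 1 / (1 + exp(-z))
  choice <- if (runif(1) < p_left) "left" else "right"
  list(choice = choice, d_left = d_left, d_right = d_right,
       p_left = p_left)
}

#' Run the synaptic-plasticity circuit through a task session
#'
#' Per trial: the action is selected by probing the onset neurons with the
#' weights carried over from the previous trial; the chosen side's
#' sequence is generated from the input profile (or replaced by
#' stimulation on a random `stim_frac` of trials); value, RPE, eligibility
#' and weights are integrated from `t_start ~ N(-2.5, 0.2^2)` to +3 s
#' around the press at dt = 0.01 s (eligibility reset at trial start,
#' weights carried across trials); the outcome follows the task's block
#' rules and feeds back as the truncated-Gaussian reward input.
#'
#' @param profile a [sequence_profile()] describing the input population
#' @param task a [task_config()]
#' @param params a [plasticity_params()]
#' @param n_trials number of trials
#' @param stim_frac fraction of trials with optogenetic-like stimulation
#'   (rate clamped to 0.2 on 70% of neurons from the nose poke to 2 s
#'   after reward feedback)
#' @param stim_fraction_neurons fraction of neurons stimulated on a
#'   stimulation trial
#' @param init_w initial weights (default 0; performance does not depend
#'   on the choice)
#' @param trace_trials trial indices for which to keep the full value/RPE
#'   traces
#' @return a `cs_plasticity_run` list: `session` (a `cs_session`),
#'   `trials` (per-trial decision variables, probabilities and
#'   feedback-window RPE), final `w_hat`/`w`, and `traces` for the
#'   requested trials
#' @export
run_plasticity_session <- function(profile, task = task_config(),
                                   params = plasticity_params(),
                                   n_trials = 5000L, stim_frac = 0,
                                   stim_fraction_neurons = 0.7,
                                   init_w = NULL,
                                   trace_trials = integer(0)) {
  if (!is_count(n_trials)) stopf("invalid config: n_trials must be >= 1")
  n <- 2L * profile$n_per_side
  labels <- rep(c("left", "right"), each = profile$n_per_side)
  peaks <- rep(profile$peaks, 2)
  sp <- smoothed_bump_pars(profile)
  w_hat <- if (is.null(init_w)) numeric(n) else rep_len(init_w, n)
  st <- task_state_init(task)
  prev <- "none"
  t_lo <- profile$t_range[1]

  cols <- c("choice", "outcome", "block", "stimulated")
  choice <- character(n_trials); outcome <- integer(n_trials)
  block <- character(n_trials); stim_fl <- logical(n_trials)
  d_left <- numeric(n_trials); d_right <- numeric(n_trials)
  p_left <- numeric(n_trials); rpe_fb <- numeric(n_trials)
  rpe_int <- numeric(n_trials)
  ev <- matrix(NA_real_, n_trials, 5,
               dimnames = list(NULL, c("nose_poke", "levers_out",
                                       "lever_press", "cs",
                                       "reward_consumption")))
  traces <- list()

  for (i in seq_len(n_trials)) {
    w <- pmax(0, w_hat)
    act <- select_action(w, peaks, labels, prev, params)
    ch <- act$choice
    block[i] <- st$block
    out <- task_draw_outcome(st, ch)

    t_start <- min(max(rnorm(1, params$t_start_mean, params$t_start_sd),
                       t_lo), -1.5)
    lev <- min(t_start + sample(seq(0, 1, by = 0.1), 1L), -0.1)
    cs <- runif(1, 0, 1)
    mu_r <- runif(1, params$reward_mu_range[1], params$reward_mu_range[2])
    t_grid <- seq(t_start, params$t_end, by = params$dt)
    r <- reward_kernel(out, t_grid, mu_r, params$reward_sigma)

    jit <- rnorm(n, 0, profile$peak_jitter_sd)
    ampn <- if (profile$amplitude_noise_sd > 0)
      rtnorm0(n, 1, profile$amplitude_noise_sd) else rep(1, n)
    amp <- ampn * profile$peak_amplitude *
      ifelse(labels == ch, 1, profile$selectivity) * sp$amp

    stim_i <- stim_frac > 0 && runif(1) < stim_frac
    stim_sel <- if (stim_i)
      sample.int(n, round(stim_fraction_neurons * n)) else integer(0)

    res <- plasticity_trial_cpp(peaks + jit, amp, sp$sd, w_hat,
                                as.integer(stim_sel), 0.2,
                                t_start, params$t_end,
                                t_start, params$t_end, params$dt, r,
                                params$alpha, params$tau_discount,
                                params$tau_e, params$delta,
                                isTRUE(params$floor_each_step))
    w_hat <- res$w_hat
    fb <- t_grid >= cs + 0.2 & t_grid <= cs + 1.2
    rpe_fb[i] <- mean(res$rpe[fb])
    rpe_int[i] <- sum(res$rpe) * params$dt
    if (i %in% trace_trials)
      traces[[as.character(i)]] <- list(time = t_grid, value = res$value,
                                        rpe = res$rpe, outcome = out,
                                        cs = cs, mu_r = mu_r)

    choice[i] <- ch; outcome[i] <- out; stim_fl[i] <- stim_i
    d_left[i] <- act$d_left; d_right[i] <- act$d_right
    p_left[i] <- act$p_left
    ev[i, ] <- c(t_start, lev, 0, cs,
                 if (out == 1) cs + 0.5 else NA_real_)
    st <- task_advance(st, out)
    prev <- ch
  }
  trials <- data.frame(trial = seq_len(n_trials), choice = choice,
                       outcome = outcome, block = block,
                       stimulated = stim_fl)
  session <- as_cs_session(cbind(trials, as.data.frame(ev)), task)
  structure(list(session = session,
                 stats = data.frame(trial = seq_len(n_trials),
                                    d_left = d_left, d_right = d_right,
                                    p_left = p_left, rpe_fb = rpe_fb,
                                    rpe_integral = rpe_int),
                 w_hat = w_hat, w = pmax(0, w_hat),
                 peak_times = peaks, side_labels = labels,
                 traces = traces, params = params, profile = profile),
            class = "cs_plasticity_run")
}

#' @export
print.cs_plasticity_run <- function(x, ...) {
  s <- x$session
  cat(sprintf(
    "<cs_plasticity_run> %d trials, reward rate %.1f%%, mean block %.1f trials\n",
    nrow(s), 100 * mean(s$outcome), mean_block_length(s)))
  invisible(x)
}

# Pure-R reference integration of one trial; mirrors plasticity_trial_cpp
# step for step and is used to validate it.
plasticity_trial_ref <- function(mu, amp, sd_eff, w_hat, stim_sel,
                                 stim_value, stim_on, stim_off, t_start,
                                 t_end, dt, r, params,
                                 floor_each_step = TRUE) {
  n_steps <- length(r)
  n <- length(mu)
  stim <- logical(n); stim[stim_sel] <- TRUE
  E <- numeric(n)
  v_trace <- numeric(n_steps); d_trace <- numeric(n_steps)
  m <- round(params$delta / dt)
  for (k in seq_len(n_steps)) {
    t <- t_start + (k - 1) * dt
    z <- (t - mu) / sd_eff
    f <- amp * exp(-0.5 * z^2)
    if (t >= stim_on && t <= stim_off) f[stim] <- stim_value
    V <- sum(pmax(0, w_hat) * f)
    V_del <- if (k - m >= 1) v_trace[k - m] else 0
    delta <- compute_rpe(V, V_del, r[k], params)
    v_trace[k] <- V; d_trace[k] <- delta
    E <- update_eligibility(E, f, params)
    w_hat <- update_weights(w_hat, delta, E, params$alpha, dt)$w_hat
    if (floor_each_step) w_hat <- pmax(0, w_hat)
  }
  list(w_hat = w_hat, value = v_trace, rpe = d_trace)
}
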