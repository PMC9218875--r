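# Synthetic single-trial choice-selective population sequences and
# event-locked fluorescence with known ground-truth kernels.

#' Sequence profile for synthetic choice-selective population activity
#'
#' Parameterizes a population of `2 * n_per_side` model neurons (half
#' left-, half right-choice-preferring) whose Gaussian rate bumps tile the
#' peri-press window. On each trial the chosen side's neurons emit bumps of
#' nominal peak `peak_amplitude` at their tiled peak times, perturbed by
#' per-trial peak jitter and multiplicative amplitude noise; the unchosen
#' side emits the same shape scaled by `selectivity`. The resulting rates
#' are smoothed with a zero-mean Gaussian kernel of width `smoothing_sd`.
#'
#' @param n_per_side neurons per side (default 184)
#' @param span two-element vector of peak-time tiling range, seconds
#'   relative to the lever press (default -2 to +3)
#' @param peak_amplitude nominal bump peak before smoothing, in the
#'   normalized (z-scored-like) rate units of the model. Transient
#'   z-scored firing rates peak well above 1, and the circuit model's
#'   learning speed scales with the squared activity amplitude; the
#'   default is calibrated once so the cortical-like preset supports the
#'   published circuit-model reward rate (see the methods vignette)
#' @param bump_width Gaussian bump standard deviation, seconds
#' @param selectivity amplitude ratio of the unchosen side in `[0, 1]`
#' @param peak_jitter_sd per-trial peak-time jitter, seconds
#' @param amplitude_noise_sd multiplicative amplitude noise (truncated
#'   normal around 1)
#' @param smoothing_sd smoothing kernel sd, seconds (default 0.2)
#' @param dt sample step, seconds
#' @param t_range two-element time grid range (left-edge-labeled, half-open
#'   bins, t = 0 at the lever press)
#' @return a `cs_seq_profile` object
#' @export
sequence_profile <- function(n_per_side = 184L, span = c(-2, 3),
                             peak_amplitude = 1.4,
                             bump_width = 0.3, selectivity = 0.1,
                             peak_jitter_sd = 0.05,
                             amplitude_noise_sd = 0.2,
                             smoothing_sd = 0.2, dt = 0.01,
                             t_range = c(-3, 3)) {
  if (!is_prob(selectivity)) stopf("selectivity must be in [0, 1]")
  if (dt <= 0) stopf("dt must be positive")
  peaks <- seq(span[1], span[2], length.out = n_per_side)
  if (any(diff(peaks) <= 0) && n_per_side > 1)
    stopf("peak times must be strictly increasing within a side")
  structure(list(n_per_side = as.integer(n_per_side), span = span,
                 peak_amplitude = peak_amplitude,
                 peaks = peaks, bump_width = bump_width,
                 selectivity = selectivity,
                 peak_jitter_sd = peak_jitter_sd,
                 amplitude_noise_sd = amplitude_noise_sd,
                 smoothing_sd = smoothing_sd, dt = dt, t_range = t_range),
            class = "cs_seq_profile")
}

#' Named presets emulating the recorded input populations
#'
#' * `pl_like`: highly consistent sequences tiling the full -2..+3 s span
#'   with low jitter and strong choice selectivity (unchosen side at 10%).
#' * `mth_like`: same span but much less consistent (peak jitter >= 0.5 s,
#'   higher amplitude noise) and weakly selective (unchosen side at 50%).
#' * `early_only`: all peaks compressed into the 0.5 s at the start of the
#'   sequence (onset near -2.5 s relative to the press), otherwise like
#'   `pl_like`; only sequence-onset neurons are active.
#'
#' @param name preset name
#' @param n_per_side optional override of the population size
#' @return a `cs_seq_profile`
#' @export
make_profile_preset <- function(name = c("pl_like", "mth_like",
                                         "early_only"),
                                n_per_side = 184L) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stopf("unknown preset name"))
  switch(name,
    pl_like = sequence_profile(n_per_side = n_per_side),
    mth_like = sequence_profile(n_per_side = n_per_side,
                                selectivity = 0.5, peak_jitter_sd = 0.6,
                                amplitude_noise_sd = 0.6),
    early_only = sequence_profile(n_per_side = n_per_side,
                                  span = c(-2.5, -2.0)))
}

# Analytic Gaussian smoothing: a Gaussian bump of sd b convolved with a
# normalized Gaussian kernel of sd s is a Gaussian of sd sqrt(b^2 + s^2)
# scaled by b / sqrt(b^2 + s^2).
smoothed_bump_pars <- function(profile) {
  b <- profile$bump_width; s <- profile$smoothing_sd
  sd_eff <- sqrt(b^2 + s^2)
  list(sd = sd_eff, amp = b / sd_eff)
}

#' Generate one trial of choice-selective population activity
#'
#' @param side `"left"` or `"right"`, the chosen lever
#' @param profile a [sequence_profile()]
#' @param smoothing `"analytic"` evaluates the Gaussian-smoothed bumps in
#'   closed form; `"discrete"` builds the raw bumps on the grid and
#'   convolves with a discrete normalized Gaussian kernel (reference
#'   implementation, used for validation)
#' @return a `cs_pop_activity` list: `rates` (neuron x time matrix, >= 0),
#'   `side_labels`, `peak_times` (configured peaks), `dt`, `t0`, `time`
#' @export
generate_sequence_trial <- function(side = c("left", "right"), profile,
                                    smoothing = c("analytic", "discrete")) {
  side <- match.arg(side)
  smoothing <- match.arg(smoothing)
  n <- profile$n_per_side
  time <- seq(profile$t_range[1], profile$t_range[2] - profile$dt,
              by = profile$dt)
  labels <- rep(c("left", "right"), each = n)
  peaks <- rep(profile$peaks, 2)
  jit <- rnorm(2 * n, 0, profile$peak_jitter_sd)
  amp <- if (profile$amplitude_noise_sd > 0)
    rtnorm0(2 * n, 1, profile$amplitude_noise_sd) else rep(1, 2 * n)
  amp <- amp * profile$peak_amplitude *
    ifelse(labels == side, 1, profile$selectivity)
  mu <- peaks + jit
  if (smoothing == "analytic") {
    sp <- smoothed_bump_pars(profile)
    z <- outer(mu, time, function(m, t) (t - m) / sp$sd)
    rates <- amp * sp$amp * exp(-0.5 * z^2)
    rates[abs(z) > 6] <- 0
  } else {
    z <- outer(mu, time, function(m, t) (t - m) / profile$bump_width)
    raw <- amp * exp(-0.5 * z^2)
    ks <- profile$smoothing_sd / profile$dt
    half <- ceiling(4 * ks)
    kern <- dnorm(seq(-half, half), 0, ks)
    kern <- kern / sum(kern)
    rates <- t(apply(raw, 1, function(r) {
      padded <- c(rep(0, half), r, rep(0, half))
      stats::convolve(padded, rev(kern), type = "filter")
    }))
  }
  structure(list(rates = pmax(rates, 0), side_labels = labels,
                 peak_times = peaks, dt = profile$dt, t0 = time[1],
                 time = time, side = side),
            class = "cs_pop_activity")
}

#' Apply optogenetic-like stimulation to population activity
#'
#' Emulates channelrhodopsin stimulation with incomplete viral penetrance:
#' a random `fraction` of neurons (both sides pooled) has its rate replaced
#' by a constant. In `"plasticity"` mode the constant is 0.2 and applies
#' from the simulated nose poke until 2 s after reward feedback
#' (`t_on`/`t_off`); in `"dynamics"` mode it is 0.15 for the whole trial.
#'
#' @param activity a `cs_pop_activity`
#' @param mode `"plasticity"` or `"dynamics"`
#' @param fraction fraction of neurons stimulated (default 0.7)
#' @param t_on,t_off stimulation window in seconds relative to the press
#'   (plasticity mode)
#' @return the modified `cs_pop_activity`, with the selected neuron indices
#'   in `$stim_neurons`
#' @export
apply_stimulation <- function(activity, mode = c("plasticity", "dynamics"),
                              fraction = 0.7, t_on = -2.5, t_off = 3) {
  mode <- match.arg(mode)
  if (!is_prob(fraction)) stopf("fraction must be in [0, 1]")
  n <- nrow(activity$rates)
  n_sel <- round(fraction * n)
  sel <- if (n_sel > 0) sample.int(n, n_sel) else integer(0)
  if (length(sel)) {
    if (mode == "plasticity") {
      cols <- which(activity$time >= t_on & activity$time <= t_off)
      activity$rates[sel, cols] <- 0.2
    } else {
      activity$rates[sel, ] <- 0.15
    }
  }
  activity$stim_neurons <- sel
  activity
}

#' Split-half consistency of sequential activity
#'
#' Splits trials into random halves, computes each neuron's time of peak
#' trial-averaged activity in each half, and returns the squared Pearson
#' correlation between the two sets of peak times (the benchmark statistic
#' for sequence consistency; the recorded cortical population reaches
#' about 0.8).
#'
#' @param trials list of `cs_pop_activity` from repeated trials of the same
#'   population
#' @param min_rate neurons whose peak activity in either half falls below
#'   this are excluded (reported in `n_excluded`)
#' @return list with `r_squared`, `n_used`, `n_excluded`, and the per-half
#'   peak times
#' @export
sequence_consistency <- function(trials, min_rate = 1e-6) {
  if (length(trials) < 20) stopf("need at least 20 trials")
  n_tr <- length(trials)
  half <- sample.int(n_tr, floor(n_tr / 2))
  avg <- function(idx) Reduce(`+`, lapply(trials[idx], `[[`, "rates")) /
    length(idx)
  a1 <- avg(half); a2 <- avg(setdiff(seq_len(n_tr), half))
  time <- trials[[1]]$time
  pk <- function(a) list(t = time[max.col(a, ties.method = "first")],
                         amp = apply(a, 1, max))
  p1 <- pk(a1); p2 <- pk(a2)
  keep <- p1$amp > min_rate & p2$amp > min_rate
  if (sum(keep) < 3) stopf("too few active neurons for consistency")
  r2 <- cor(p1$t[keep], p2$t[keep])^2
  list(r_squared = r2, n_used = sum(keep), n_excluded = sum(!keep),
       peaks_half1 = p1$t, peaks_half2 = p2$t)
}

# ---- event-locked fluorescence with known ground-truth kernels ----------

#' Ground-truth kernel set for encoding-model validation
#'
#' @param kernels named list of event kernels; each element is a list with
#'   `kernel` (numeric vector sampled at `rate`) and `window` (two-element
#'   vector, seconds relative to the event; -2..6 for actions, 0..8 for
#'   stimuli)
#' @param noise_sd additive i.i.d. Gaussian noise sd on each trace
#' @return a `cs_truth_kernels` object
#' @export
ground_truth_kernels <- function(kernels, noise_sd = 0.1) {
  for (nm in names(kernels)) {
    k <- kernels[[nm]]
    want <- round(diff(k$window) * 10) + 1
    if (length(k$kernel) != want)
      stopf("kernel '%s' must have %d samples for its window", nm, want)
  }
  structure(list(kernels = kernels, noise_sd = noise_sd),
            class = "cs_truth_kernels")
}

#' Generate event-locked fluorescence traces from known kernels
#'
#' Each simulated neuron's trace is the sum, over the events it is assigned
#' to, of the ground-truth kernel convolved with the binary event train,
#' plus i.i.d. Gaussian noise; traces are z-scored by their session mean
#' and sd, at 10 Hz. This is the generative control used to validate the
#' encoding model (e.g. neurons that respond only to lever presses).
#'
#' @param session a `cs_session` with event-time columns
#' @param truth a [ground_truth_kernels()]
#' @param n_neurons number of neurons to simulate
#' @param assignments optional list (length `n_neurons`) of event-name
#'   vectors; by default every neuron responds to every event in `truth`
#' @param rate sampling rate, Hz
#' @return list with `traces` (time x neuron matrix, z-scored), `trains`
#'   (binary event trains), `time`, `assignments`
#' @export
generate_event_stream_session <- function(session, truth, n_neurons = 1L,
                                          assignments = NULL, rate = 10) {
  trains <- event_trains_from_session(session, rate = rate,
                                      events = names(truth$kernels))
  T_len <- length(trains$time)
  if (is.null(assignments))
    assignments <- rep(list(names(truth$kernels)), n_neurons)
  clean <- matrix(0, T_len, n_neurons)
  for (j in seq_len(n_neurons)) {
    for (ev in assignments[[j]]) {
      k <- truth$kernels[[ev]]
      clean[, j] <- clean[, j] +
        convolve_train(trains$trains[[ev]], k$kernel, k$window, rate)
    }
  }
  traces <- clean + matrix(rnorm(T_len * n_neurons, 0, truth$noise_sd),
                           T_len, n_neurons)
  traces <- scale(traces)
  traces[is.nan(traces)] <- 0
  list(traces = traces, clean = clean, trains = trains$trains,
       time = trains$time, assignments = assignments)
}

# place kernel (aligned so sample 1 sits at window[1] relative to the
# event) onto the session grid for each event occurrence
convolve_train <- function(train, kernel, window, rate) {
  out <- numeric(length(train))
  off <- round(window[1] * rate)
  at <- which(train > 0)
  for (s in at) {
    idx <- s + off + seq_along(kernel) - 1L
    ok <- idx >= 1 & idx <= length(out)
    out[idx[ok]] <- out[idx[ok]] + kernel[ok]
  }
  out
}
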