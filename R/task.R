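# Probabilistic reversal learning task: block structure, reward draws and
# behavioral summaries.

#' Task configuration for the probabilistic reversal task
#'
#' Describes the two-lever probabilistic reversal task. On each trial one
#' lever is the high-probability ("block") lever rewarded with probability
#' `p_high`, the other with `p_low`. Three reversal rules are supported:
#'
#' * `reward_counted` (the behavioral task): the block reverses after
#'   `rewards_to_reversal` rewarded trials plus a geometric number of
#'   additional trials with success probability `geometric_p`
#'   (support starting at k = 1).
#' * `geometric_only`: block length is drawn directly from the same
#'   geometric distribution, regardless of rewards (used to make reversals
#'   unpredictable when training the recurrent network model).
#' * `per_trial_hazard`: the block state flips i.i.d. with probability
#'   `hazard` on each trial (the hidden-state process assumed by the ideal
#'   observer comparisons).
#'
#' @param p_high,p_low reward probabilities of the high- and low-probability
#'   levers; defaults 0.7 and 0.1 (the "70-10" stage). Use 1 and 0 for the
#'   deterministic "100-0" training stage.
#' @param rewards_to_reversal rewarded trials required before the geometric
#'   extension starts (default 10)
#' @param geometric_p success probability of the geometric extension
#'   (default 0.4)
#' @param variant reversal rule, see above
#' @param hazard per-trial reversal probability for `per_trial_hazard`
#' @return an object of class `cs_task_config`
#' @export
task_config <- function(p_high = 0.7, p_low = 0.1, rewards_to_reversal = 10,
                        geometric_p = 0.4,
                        variant = c("reward_counted", "geometric_only",
                                    "per_trial_hazard"),
                        hazard = 0.05) {
  variant <- match.arg(variant)
  if (!is_prob(p_high) || !is_prob(p_low) || p_low >= p_high)
    stopf("invalid config: need 0 <= p_low < p_high <= 1")
  if (!is.numeric(geometric_p) || geometric_p <= 0 || geometric_p > 1)
    stopf("invalid config: geometric_p must be in (0, 1]")
  if (!is_count(rewards_to_reversal))
    stopf("invalid config: rewards_to_reversal must be a count >= 1")
  if (variant == "per_trial_hazard" && !is_prob(hazard))
    stopf("invalid config: hazard must be a probability")
  structure(list(p_high = p_high, p_low = p_low,
                 rewards_to_reversal = rewards_to_reversal,
                 geometric_p = geometric_p, variant = variant,
                 hazard = hazard),
            class = "cs_task_config")
}

#' Sample the geometric block extension
#'
#' Number of trials k >= 1 with P(k) = (1 - p)^(k - 1) * p. A reversal can
#' never occur on the same trial as the final required reward, so the
#' support starts at 1.
#'
#' @param p success probability in (0, 1]
#' @param n number of draws
#' @return integer vector of draws
#' @export
sample_block_extension <- function(p, n = 1L) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stopf("invalid config: p must be in (0, 1]")
  rgeom(n, p) + 1L
}

#' Expected reward rate of a side-blind policy
#'
#' A policy whose choices are independent of the block identity is rewarded
#' at `(p_high + p_low) / 2`; for the 70/10 task this is the 40% chance
#' rate.
#'
#' @param config a [task_config()]
#' @return scalar fraction
#' @export
chance_reward_rate <- function(config) {
  (config$p_high + config$p_low) / 2
}

# -- internal task state machine (shared with the circuit models) ---------

task_state_init <- function(config, first_block = NULL) {
  if (is.null(first_block))
    first_block <- if (runif(1) < 0.5) "left_high" else "right_high"
  st <- list(config = config, block = first_block, rewards_in_block = 0L,
             extension_left = NA_integer_, block_trials = 0L)
  if (config$variant == "geometric_only")
    st$extension_left <- sample_block_extension(config$geometric_p)
  st
}

task_draw_outcome <- function(state, choice) {
  if (choice == "none") return(0L)
  cfg <- state$config
  high <- (state$block == "left_high" && choice == "left") ||
          (state$block == "right_high" && choice == "right")
  p <- if (high) cfg$p_high else cfg$p_low
  as.integer(runif(1) < p)
}

# Advance the block state after a completed trial. Returns the state; the
# `reversed` field flags that the *next* trial starts a new block.
task_advance <- function(state, outcome) {
  cfg <- state$config
  state$block_trials <- state$block_trials + 1L
  state$reversed <- FALSE
  flip <- function(b) if (b == "left_high") "right_high" else "left_high"
  if (cfg$variant == "reward_counted") {
    if (is.na(state$extension_left)) {
      state$rewards_in_block <- state$rewards_in_block + outcome
      if (state$rewards_in_block >= cfg$rewards_to_reversal)
        state$extension_left <- sample_block_extension(cfg$geometric_p)
    } else {
      state$extension_left <- state$extension_left - 1L
      if (state$extension_left <= 0L) {
        state$block <- flip(state$block)
        state$rewards_in_block <- 0L
        state$extension_left <- NA_integer_
        state$block_trials <- 0L
        state$reversed <- TRUE
      }
    }
  } else if (cfg$variant == "geometric_only") {
    state$extension_left <- state$extension_left - 1L
    if (state$extension_left <= 0L) {
      state$block <- flip(state$block)
      state$extension_left <- sample_block_extension(cfg$geometric_p)
      state$block_trials <- 0L
      state$reversed <- TRUE
    }
  } else { # per_trial_hazard
    if (runif(1) < cfg$hazard) {
      state$block <- flip(state$block)
      state$block_trials <- 0L
      state$reversed <- TRUE
    }
  }
  state
}

# Within-trial event times relative to the lever press (t = 0).
# Nose poke ~ N(-2.5, 0.2); nose poke -> levers out uniform on the 0.1 s
# grid from 0 to 1 s; press -> CS uniform 0-1 s; reward consumption starts
# 0.5 s after the CS on rewarded trials.
draw_event_times <- function(outcome) {
  np <- min(rnorm(1, -2.5, 0.2), -1.3)
  lev <- np + sample(seq(0.1, 1, by = 0.1), 1L)
  lev <- min(lev, -0.1)
  cs <- runif(1, 0, 1)
  c(nose_poke = np, levers_out = lev, lever_press = 0, cs = cs,
    reward_consumption = if (outcome == 1) cs + 0.5 else NA_real_)
}

#' Simulate a session of the probabilistic reversal task
#'
#' Runs `n_trials` of the task under a caller-supplied policy. The policy is
#' called as `policy(i, prev_choice, prev_outcome)` and must return
#' `"left"`, `"right"` or `"none"`; abandoned (`"none"`) trials are recorded
#' with outcome 0 and do not advance the block state.
#'
#' @param policy callable, see above
#' @param config a [task_config()]
#' @param n_trials number of trials (>= 1)
#' @param first_block optional `"left_high"` / `"right_high"` override of
#'   the fair-coin first block
#' @param events if `TRUE`, draw within-trial event times for each trial
#' @return a `cs_session` object: a data frame of trials (`trial`, `choice`,
#'   `outcome`, `block`, `stimulated`, and event-time columns) with the
#'   config attached as an attribute
#' @export
run_session <- function(policy, config = task_config(), n_trials,
                        first_block = NULL, events = TRUE) {
  if (!is_count(n_trials)) stopf("invalid config: n_trials must be >= 1")
  st <- task_state_init(config, first_block)
  choice <- character(n_trials); outcome <- integer(n_trials)
  block <- character(n_trials)
  ev <- matrix(NA_real_, n_trials, 5,
               dimnames = list(NULL, c("nose_poke", "levers_out",
                                       "lever_press", "cs",
                                       "reward_consumption")))
  prev_c <- "none"; prev_o <- 0L
  for (i in seq_len(n_trials)) {
    ch <- policy(i, prev_c, prev_o)
    block[i] <- st$block
    out <- task_draw_outcome(st, ch)
    choice[i] <- ch; outcome[i] <- out
    if (events) ev[i, ] <- draw_event_times(out)
    if (ch != "none") st <- task_advance(st, out)
    prev_c <- ch; prev_o <- out
  }
  trials <- data.frame(trial = seq_len(n_trials), choice = choice,
                       outcome = outcome, block = block,
                       stimulated = FALSE)
  if (events) trials <- cbind(trials, as.data.frame(ev))
  as_cs_session(trials, config)
}

as_cs_session <- function(trials, config) {
  structure(trials, config = config, class = c("cs_session", "data.frame"))
}

#' @export
print.cs_session <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<cs_session> %d trials, variant %s (%.0f/%.0f%%), %.1f%% rewarded\n",
              nrow(x), cfg$variant, 100 * cfg$p_high, 100 * cfg$p_low,
              100 * mean(x$outcome[x$choice != "none"])))
  invisible(x)
}

#' Stay probability stratified by previous outcome (and stimulation)
#'
#' Fraction of trials on which the choice repeats the previous trial's
#' choice, stratified by the previous trial's outcome. With
#' `split_by = "outcome_x_stimulation"` the table is additionally
#' stratified by the stimulation flag of the previous trial and, in a
#' second set of rows, of the current trial. Trials following an abandoned
#' trial are excluded; an empty stratum yields `NA`, not zero.
#'
#' @param session a `cs_session`
#' @param split_by `"outcome"` or `"outcome_x_stimulation"`
#' @return data frame with columns `prev_outcome`, (`stim_ref`, `stim`,)
#'   `stay`, `n`
#' @export
stay_probability <- function(session,
                             split_by = c("outcome",
                                          "outcome_x_stimulation")) {
  split_by <- match.arg(split_by)
  ok <- session$choice != "none"
  if (sum(ok) < 2) stopf("need at least 2 non-abandoned trials")
  i <- which(ok)[-1]
  prev <- i - 1L
  usable <- session$choice[prev] != "none"
  i <- i[usable]; prev <- prev[usable]
  stay <- session$choice[i] == session$choice[prev]
  po <- session$outcome[prev]
  frac <- function(idx) if (length(idx)) mean(stay[idx]) else NA_real_
  if (split_by == "outcome") {
    return(data.frame(prev_outcome = c(0L, 1L),
                      stay = c(frac(which(po == 0)), frac(which(po == 1))),
                      n = c(sum(po == 0), sum(po == 1))))
  }
  ps <- session$stimulated[prev]
  csx <- session$stimulated[i]
  grid <- expand.grid(prev_outcome = c(0L, 1L), stim = c(FALSE, TRUE),
                      stim_ref = c("previous", "current"),
                      stringsAsFactors = FALSE)
  grid$stay <- NA_real_; grid$n <- 0L
  for (r in seq_len(nrow(grid))) {
    sflag <- if (grid$stim_ref[r] == "previous") ps else csx
    idx <- which(po == grid$prev_outcome[r] & sflag == grid$stim[r])
    grid$stay[r] <- frac(idx); grid$n[r] <- length(idx)
  }
  grid[, c("prev_outcome", "stim_ref", "stim", "stay", "n")]
}

#' Choice probability around block reversals
#'
#' P(choose left) and P(choose right) at each trial lag in
#' `[-window, +window]` around block reversals (lag 0 is the first trial of
#' the new block), averaged separately over left-to-right and
#' right-to-left reversals. Lags that fall outside the session or into a
#' neighbouring reversal's territory are averaged over the reversals that
#' do provide them.
#'
#' @param session a `cs_session`
#' @param window number of trials on each side of the reversal
#' @return data frame with columns `direction`, `lag`, `p_left`, `p_right`,
#'   `n`
#' @export
reversal_aligned_choice_prob <- function(session, window = 10L) {
  blk <- session$block
  rev_idx <- which(blk[-1] != blk[-length(blk)]) + 1L
  if (!length(rev_idx)) stopf("session contains no reversal")
  dirs <- ifelse(blk[rev_idx] == "right_high", "left_to_right",
                 "right_to_left")
  lags <- seq.int(-window, window)
  out <- expand.grid(direction = c("left_to_right", "right_to_left"),
                     lag = lags, stringsAsFactors = FALSE)
  out$p_left <- NA_real_; out$p_right <- NA_real_; out$n <- 0L
  for (r in seq_len(nrow(out))) {
    idx <- rev_idx[dirs == out$direction[r]] + out$lag[r]
    idx <- idx[idx >= 1 & idx <= nrow(session)]
    ch <- session$choice[idx]
    ch <- ch[ch != "none"]
    if (length(ch)) {
      out$p_left[r] <- mean(ch == "left")
      out$p_right[r] <- mean(ch == "right")
      out$n[r] <- length(ch)
    }
  }
  out[order(out$direction, out$lag), ]
}

#' Trials taken to cross 50% choice of the newly favoured lever
#'
#' Summary of the reversal-aligned curve: the first non-negative lag at
#' which the probability of choosing the newly high-probability lever
#' reaches 0.5. `NA` when it never crosses within the window.
#'
#' @param curve result of [reversal_aligned_choice_prob()]
#' @return scalar lag (trials)
#' @export
reversal_crossing_lag <- function(curve) {
  lag_for <- function(direction, col) {
    d <- curve[curve$direction == direction & curve$lag >= 0, ]
    d <- d[order(d$lag), ]
    hit <- which(d[[col]] >= 0.5)
    if (length(hit)) d$lag[hit[1]] else NA_real_
  }
  mean(c(lag_for("left_to_right", "p_right"),
         lag_for("right_to_left", "p_left")), na.rm = TRUE)
}

#' Mean block length of a session
#'
#' @param session a `cs_session`
#' @return mean number of trials between consecutive reversals
#' @export
mean_block_length <- function(session) {
  blk <- session$block
  bounds <- c(0L, which(blk[-1] != blk[-length(blk)]), length(blk))
  lens <- diff(bounds)
  # the final, censored block is dropped when at least one full block exists
  if (length(lens) > 1) lens <- lens[-length(lens)]
  mean(lens)
}

#' Write / read a session as CSV
#'
#' Sessions are persisted as plain CSV with one row per trial: `trial`,
#' `choice`, `outcome`, `block`, `stimulated` plus one column per
#' within-trial event time.
#'
#' @param session a `cs_session`
#' @param path file path
#' @export
write_session_csv <- function(session, path) {
  utils::write.csv(as.data.frame(session), path, row.names = FALSE)
}

#' @rdname write_session_csv
#' @param config a [task_config()] to attach on read
#' @export
read_session_csv <- function(path, config = task_config()) {
  as_cs_session(utils::read.csv(path, stringsAsFactors = FALSE), config)
}

# Absolute event times across a session (seconds from session start),
# spacing trials by a 2 s inter-trial interval after the CS / reward
# consumption. Used to build 10 Hz event trains for the encoding model.
session_absolute_events <- function(session, iti = 2) {
  n <- nrow(session)
  press <- numeric(n)
  ends <- ifelse(is.na(session$reward_consumption),
                 session$cs + 0.5, session$reward_consumption + 2)
  press[1] <- -session$nose_poke[1] + 0.5
  if (n > 1) {
    for (i in 2:n) {
      press[i] <- press[i - 1] + ends[i - 1] + iti - session$nose_poke[i]
    }
  }
  cols <- c("nose_poke", "levers_out", "lever_press", "cs",
            "reward_consumption")
  abs_ev <- sapply(cols, function(cl) press + session[[cl]])
  colnames(abs_ev) <- cols
  as.data.frame(abs_ev)
}

#' Read a task configuration from a YAML file
#'
#' Convenience loader for persisted task configs (see
#' `inst/extdata/task_70_10.yaml` for the final-stage behavioral task).
#'
#' @param path YAML file with fields matching [task_config()]'s arguments
#' @return a [task_config()]
#' @export
read_task_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  do.call(task_config, cfg)
}
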