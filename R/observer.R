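# Bayesian ideal observer and Q-learning on the reversal tasks, their
# trial-level reward prediction errors, and the block-reversal comparison.

#' Ideal-observer configuration
#'
#' Known generative model of the hidden block state: a symmetric two-state
#' transition matrix with per-trial reversal probability `hazard`, and a
#' reward matrix R[state, choice] giving P(reward = 1). `task = "bromberg"`
#' uses the deterministic 100/0 rewards; `task = "ours"` the 70/10 rewards.
#'
#' @param task `"ours"` (70/10) or `"bromberg"` (100/0)
#' @param hazard per-trial reversal probability (default 0.05)
#' @return a `cs_observer_config`
#' @export
observer_config <- function(task = c("ours", "bromberg"), hazard = 0.05) {
  task <- match.arg(task)
  Tm <- matrix(c(1 - hazard, hazard, hazard, 1 - hazard), 2, 2,
               byrow = TRUE,
               dimnames = list(c("left_high", "right_high"),
                               c("left_high", "right_high")))
  Rm <- if (task == "bromberg") matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
        else matrix(c(0.7, 0.1, 0.1, 0.7), 2, 2, byrow = TRUE)
  dimnames(Rm) <- list(c("left_high", "right_high"), c("left", "right"))
  structure(list(T = Tm, R = Rm, task = task, hazard = hazard),
            class = "cs_observer_config")
}

#' One Bayesian belief update of the ideal observer
#'
#' Recursive posterior over the block state: the prior is propagated one
#' step through the transition matrix and multiplied by the Bernoulli
#' likelihood of the observed outcome given the choice, then normalized.
#' Under deterministic 100/0 rewards an impossible observation puts all
#' mass on the complementary state.
#'
#' @param belief numeric length-2 posterior (`left_high`, `right_high`)
#' @param choice `"left"` or `"right"`
#' @param reward observed outcome, 0 or 1
#' @param config an [observer_config()]
#' @return updated belief (sums to 1)
#' @export
observer_update <- function(belief, choice, reward, config) {
  if (any(belief < 0) || abs(sum(belief) - 1) > 1e-8)
    stopf("belief must be a probability vector")
  prior <- drop(crossprod(config$T, belief))      # sum_m T[m, j] b[m]
  lik <- config$R[, choice]^reward * (1 - config$R[, choice])^(1 - reward)
  post <- lik * prior
  z <- sum(post)
  if (z <= 0) return(stats::setNames(c(0.5, 0.5), names(belief)))
  post / z
}

#' Expected reward of each choice one trial ahead
#'
#' rho_l = sum_i R[i, l] sum_j T[j, i] belief_j: the belief is first
#' propagated through the transition matrix (the state may reverse before
#' the next trial) and then evaluated against the reward matrix.
#'
#' @inheritParams observer_update
#' @return named numeric: expected reward for `left` and `right`
#' @export
observer_expected_reward <- function(belief, config) {
  prior_next <- drop(crossprod(config$T, belief))
  drop(crossprod(config$R, prior_next))
}

#' One Q-learning update
#'
#' The chosen action's value moves toward the outcome by a fraction
#' `alpha`; the unchosen value is unchanged.
#'
#' @param q named numeric `c(left = , right = )`
#' @param choice chosen side
#' @param reward outcome, 0 or 1
#' @param alpha learning rate (default 0.612, the value fitted to mouse
#'   behavior)
#' @return updated q
#' @export
q_step <- function(q, choice, reward, alpha = 0.612) {
  q[choice] <- q[choice] + alpha * (reward - q[choice])
  q
}

#' Softmax policy over two action values with a stay bias
#'
#' P(right) = exp(bv * v_right + bs * I_right) / (sum over both sides),
#' where I is 1 for the previously chosen side. Shared by the ideal
#' observer (acting on expected rewards) and the Q-learner (acting on
#' Q-values).
#'
#' @param values named numeric `c(left = , right = )`
#' @param prev_choice previous trial's choice (`"left"`, `"right"` or
#'   `"none"`)
#' @param beta_value inverse temperature (Q-learning fit: 0.99)
#' @param beta_stay stay bias (Q-learning fit: 0.95)
#' @return named probabilities `c(left = , right = )`
#' @export
softmax_policy <- function(values, prev_choice = "none",
                           beta_value = 0.99, beta_stay = 0.95) {
  I <- c(left = 0, right = 0)
  if (prev_choice %in% names(I)) I[prev_choice] <- 1
  z <- beta_value * values[c("left", "right")] + beta_stay * I
  e <- exp(z - max(z))
  e / sum(e)
}

#' Simulate an agent on the per-trial-hazard reversal task
#'
#' Runs the ideal observer (`agent = "observer"`) or the Q-learner
#' (`agent = "q"`) for `n_trials` on a task whose block state flips with
#' the configured hazard each trial. The observer acts greedily on its
#' one-step-ahead expected rewards (ties broken at random); the Q-learner
#' acts through the softmax policy with its fitted parameters. Per-trial
#' RPE is the experienced outcome minus the expected reward of the chosen
#' action.
#'
#' @param agent `"observer"` or `"q"`
#' @param config an [observer_config()]
#' @param n_trials number of trials
#' @param policy observer action selection: `"greedy"` (default) or
#'   `"softmax"` (with the Q-learner's parameters)
#' @param q_alpha,q_beta_value,q_beta_stay Q-learner parameters
#' @return data frame with per-trial `choice`, `outcome`, `block`,
#'   `expected` (for the chosen action), `rpe`, `block_trial` (1-based
#'   trial index within its block)
#' @export
run_belief_agent <- function(agent = c("observer", "q"), config,
                             n_trials = 1000L,
                             policy = c("greedy", "softmax"),
                             q_alpha = 0.612, q_beta_value = 0.99,
                             q_beta_stay = 0.95) {
  agent <- match.arg(agent)
  policy <- match.arg(policy)
  task <- task_config(p_high = max(config$R), p_low = min(config$R),
                      variant = "per_trial_hazard",
                      hazard = config$hazard)
  st <- task_state_init(task)
  belief <- c(left_high = 0.5, right_high = 0.5)
  q <- c(left = 0, right = 0)
  prev <- "none"
  block_trial <- 1L
  out <- data.frame(choice = character(n_trials),
                    outcome = integer(n_trials),
                    block = character(n_trials),
                    expected = numeric(n_trials),
                    rpe = numeric(n_trials),
                    block_trial = integer(n_trials))
  for (i in seq_len(n_trials)) {
    if (agent == "observer") {
      rho <- observer_expected_reward(belief, config)
      if (policy == "greedy") {
        ch <- if (abs(rho["left"] - rho["right"]) < 1e-12)
          sample(c("left", "right"), 1)
        else names(rho)[which.max(rho)]
      } else {
        p <- softmax_policy(rho, prev, q_beta_value, q_beta_stay)
        ch <- if (runif(1) < p["left"]) "left" else "right"
      }
      expv <- rho[ch]
    } else {
      p <- softmax_policy(q, prev, q_beta_value, q_beta_stay)
      ch <- if (runif(1) < p["left"]) "left" else "right"
      expv <- q[ch]
    }
    r <- task_draw_outcome(st, ch)
    out$choice[i] <- ch; out$outcome[i] <- r; out$block[i] <- st$block
    out$expected[i] <- expv; out$rpe[i] <- r - expv
    out$block_trial[i] <- block_trial
    if (agent == "observer") belief <- observer_update(belief, ch, r,
                                                       config)
    else q <- q_step(q, ch, r, q_alpha)
    st <- task_advance(st, r)
    block_trial <- if (st$reversed) 1L else block_trial + 1L
    prev <- ch
  }
  out
}

#' Per-trial RPE trace of an agent run
#'
#' RPE = r(t) - expected reward of the chosen action (the belief-derived
#' expectation for the observer, the Q-value for the Q-learner).
#'
#' @param run result of [run_belief_agent()]
#' @return numeric vector
#' @export
rpe_trace <- function(run) run$rpe

#' RPE around block reversals: inference vs incremental update
#'
#' Compares the mean RPE on the first trial of a block with the mean RPE
#' on second trials whose choice differs from the first trial's choice
#' (switch trials). After such a switch the new action-outcome contingency
#' has not been experienced in the new block, so a model-based agent that
#' *infers* the reversal shows a smaller positive RPE on rewarded trial-2
#' choices than an incremental Q-learner.
#'
#' @param run result of [run_belief_agent()]
#' @param rewarded_only restrict to rewarded trials (the signature is
#'   usually read out on rewarded trial-2 choices)
#' @return list with `trial1_rpe`, `trial2_switch_rpe`, `n1`, `n2`
#' @export
reversal_rpe_summary <- function(run, rewarded_only = TRUE) {
  t1 <- which(run$block_trial == 1L)[-1]          # skip session start
  t2 <- which(run$block_trial == 2L)
  t2 <- t2[t2 > 1 & run$choice[t2] != run$choice[t2 - 1]]
  if (rewarded_only) {
    t1 <- t1[run$outcome[t1] == 1]
    t2 <- t2[run$outcome[t2] == 1]
  }
  list(trial1_rpe = if (length(t1)) mean(run$rpe[t1]) else NA_real_,
       trial2_switch_rpe = if (length(t2)) mean(run$rpe[t2]) else
         NA_real_,
       n1 = length(t1), n2 = length(t2))
}

#' Compare ideal-observer and Q-learning RPE at block reversals
#'
#' Runs both agents on the same task configuration and summarizes their
#' first-trial and post-switch second-trial RPEs.
#'
#' @param config an [observer_config()]
#' @param n_trials trials per agent
#' @return data frame with one row per agent
#' @export
reversal_rpe_comparison <- function(config, n_trials = 10000L) {
  rows <- lapply(c("observer", "q"), function(a) {
    run <- run_belief_agent(a, config, n_trials)
    s <- reversal_rpe_summary(run)
    data.frame(agent = a, trial1_rpe = s$trial1_rpe,
               trial2_switch_rpe = s$trial2_switch_rpe, n1 = s$n1,
               n2 = s$n2, reward_rate = mean(run$outcome))
  })
  do.call(rbind, rows)
}
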