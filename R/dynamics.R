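# Actor-critic neural dynamics model: configuration, initialization, A2C
# training, frozen-weight testing and actor-geometry analyses.

#' Configuration of the actor-critic recurrent network model
#'
#' The critic LSTM reads the choice-selective sequence input (one sample
#' per 0.1 s step) plus the reward; the actor LSTM reads a one-hot copy of
#' the previous action, a one-hot temporal context over the 42 steps of a
#' trial, and the dopamine RPE, and emits a 3-way policy (left / right /
#' do nothing). Each 4 s trial occupies 40 sequence steps plus a
#' decision-registration step and an end-of-trial step on which the
#' return discount is set to zero. Training uses the advantage
#' actor-critic objective with an entropy bonus, RMSprop, and geometric
#' block reversals with p = 0.9 (so reversals are unpredictable);
#' testing uses the behavioral reward-counted 70/10 block rule with
#' frozen weights.
#'
#' Defaults are desk-scale: a small network (8 units, 8 input neurons per
#' side) trained for 10,000 episodes with a 0.002 optimizer step. At this
#' scale the policy's coupling to its recurrently stored reward history
#' emerges within the episode budget; the published scale (128 units, 153
#' input neurons per side, 62,000 episodes, step 0.001) is reached by
#' overriding `n_units`, `n_per_side`, `n_episodes` and `learning_rate`.
#' The objective (loss scalings, entropy bonus, discounts, penalty,
#' trial grammar) is identical at both scales.
#'
#' @param n_units LSTM units per network
#' @param n_per_side input sequence neurons per side (peaks tiled over
#'   -2..+2 s around the press)
#' @param n_episodes training episodes
#' @param episode_trials trials per episode (15)
#' @param dt step, seconds (0.1)
#' @param beta_v,beta_e critic-loss and entropy scaling factors (0.05)
#' @param learning_rate RMSprop learning rate (published scale: 0.001
#'   per step; desk-scale default 0.002)
#' @param tau_discount within-trial discounting timescale, seconds (2.5,
#'   giving a per-step discount of exp(-0.1/2.5) ~ 0.96)
#' @param penalty reward for an action at the wrong time (-1)
#' @param input `"sequence"` for the choice-selective sequential input or
#'   `"persistent"` for the constant choice-selective control
#' @param return_form `"as_printed"` discounts the immediate reward by
#'   the current step's discount factor (the printed bootstrapped-return
#'   formula); `"conventional"` uses the standard form
#' @param geom_p_train success probability of the geometric block-length
#'   draw during training (0.1: a 10% per-trial reversal hazard, i.e. a 90%
#'   block-continuation probability, giving mean 10-trial blocks whose
#'   reversals are unpredictable on the timescale of the behavioral
#'   ~4-trial choice memory)
#' @param rho,eps RMSprop decay and stabilizer
#' @return a `cs_dynamics_config`
#' @export
dynamics_config <- function(n_units = 8L, n_per_side = 8L,
                            n_episodes = 10000L, episode_trials = 15L,
                            dt = 0.1, beta_v = 0.05, beta_e = 0.05,
                            learning_rate = 0.002, tau_discount = 2.5,
                            penalty = -1,
                            input = c("sequence", "persistent"),
                            return_form = c("as_printed",
                                            "conventional"),
                            geom_p_train = 0.1, rho = 0.9, eps = 1e-7) {
  input <- match.arg(input)
  return_form <- match.arg(return_form)
  profile <- sequence_profile(n_per_side = n_per_side, span = c(-2, 2),
                              dt = dt, t_range = c(-2, 2))
  structure(list(n_units = as.integer(n_units),
                 n_per_side = as.integer(n_per_side),
                 n_episodes = as.integer(n_episodes),
                 episode_trials = as.integer(episode_trials), dt = dt,
                 beta_v = beta_v, beta_e = beta_e,
                 learning_rate = learning_rate,
                 tau_discount = tau_discount,
                 gamma = exp(-dt / tau_discount), penalty = penalty,
                 input = input, return_form = return_form,
                 geom_p_train = geom_p_train, rho = rho, eps = eps,
                 profile = profile),
            class = "cs_dynamics_config")
}

glorot_uniform <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

orthogonal_init <- function(nrow, ncol) {
  a <- matrix(rnorm(nrow * ncol), nrow, ncol)
  if (nrow >= ncol) qr.Q(qr(a)) else t(qr.Q(qr(t(a))))
}

#' Initialize network parameters
#'
#' Input weight matrices use an orthogonal initializer, recurrent weight
#' matrices a Glorot-uniform initializer, and biases start at zero except
#' the forget-gate block, which starts at 1 (the standard unit forget
#' bias): it keeps early memory traces alive long enough for gradients to
#' discover them, which is essential here because outcome information
#' must be carried across the trial boundary to the next decision step.
#'
#' @param config a [dynamics_config()]
#' @return named list of parameter arrays
#' @export
init_dynamics_params <- function(config) {
  H <- config$n_units
  n_in <- 2L * config$n_per_side
  Dc <- n_in + 1L
  Da <- 3L + 42L + 1L
  bias0 <- function() c(rep(1, H), numeric(3 * H))
  list(Wc = orthogonal_init(4 * H, Dc),
       Uc = glorot_uniform(4 * H, H),
       bc = bias0(),
       wv = as.numeric(glorot_uniform(H, 1)),
       bv = 0,
       Wa = orthogonal_init(4 * H, Da),
       Ua = glorot_uniform(4 * H, H),
       ba = bias0(),
       Wpi = glorot_uniform(3, H),
       bpi = numeric(3))
}

# config list consumed by the C++ training / testing routines
dyn_cfg_cpp <- function(config, task = task_config()) {
  pr <- config$profile
  sp <- smoothed_bump_pars(pr)
  list(n_episodes = config$n_episodes,
       episode_trials = config$episode_trials,
       gamma = config$gamma, beta_v = config$beta_v,
       beta_e = config$beta_e, lr = config$learning_rate,
       rho = config$rho, eps = config$eps, penalty = config$penalty,
       geom_p = config$geom_p_train, p_high = task$p_high,
       p_low = task$p_low,
       rewards_to_reversal = task$rewards_to_reversal,
       mu_lo = 0.2, mu_hi = 1.2, r_sigma = 0.3, dt = config$dt,
       input_mode = if (config$input == "sequence") 0L else 1L,
       as_printed = config$return_form == "as_printed",
       peaks = rep(pr$peaks, 2),
       side = rep(c(0L, 1L), each = pr$n_per_side),
       jitter_sd = pr$peak_jitter_sd, amp_sd = pr$amplitude_noise_sd,
       selectivity = pr$selectivity, sd_eff = sp$sd,
       amp_factor = sp$amp * pr$peak_amplitude)
}

#' One LSTM step
#'
#' Gates use the logistic nonlinearity and the candidate uses tanh; the
#' memory and output states update as
#' `c' = f * c + i * tanh(W_c x + U_c h + b_c)`, `h' = o * tanh(c')`.
#' `W`, `U`, `b` stack the forget, input, output and candidate blocks
#' row-wise.
#'
#' @param W,U,b stacked gate parameters (4H x D, 4H x H, 4H)
#' @param x input vector
#' @param state list with `h` and `c`
#' @return list with updated `h` and `c`
#' @export
lstm_step <- function(W, U, b, x, state) {
  H <- length(state$h)
  if (nrow(W) != 4 * H || ncol(W) != length(x) || ncol(U) != H)
    stopf("gate/readout shapes inconsistent")
  cs_lstm_step(W, U, b, x, state$h, state$c)
}

#' Single-step RPE of the dynamics model
#'
#' delta = r + gamma V(t) - V(t - dt); the delayed value copy lags by one
#' 0.1 s simulation step, and V before the first step of an episode is 0.
#'
#' @param V_now,V_prev value at the current and previous step
#' @param r_now reward received at the current step
#' @param gamma per-step discount factor (default exp(-0.1/2.5))
#' @export
compute_rpe_dyn <- function(V_now, V_prev, r_now,
                            gamma = exp(-0.1 / 2.5)) {
  r_now + gamma * V_now - V_prev
}

#' Discounted k-step bootstrapped return
#'
#' Computes, for each step t of an episode, the return
#' `R_t = sum_i r_(t+i) prod_(j<=i) gamma_(t+j) + v_boot prod_(j<=k)
#' gamma_(t+j)` with k the number of steps remaining. In the
#' `"as_printed"` form the immediate reward is discounted by the current
#' step's factor (the published formula); `"conventional"` leaves it
#' undiscounted. With the end-of-trial discount set to zero the two forms
#' bootstrap identically at episode end.
#'
#' @param rewards per-step rewards
#' @param gammas per-step discount factors (zero at trial ends)
#' @param v_boot bootstrap value beyond the last step
#' @param gamma_boot discount factor applied beyond the last step
#' @param form `"as_printed"` or `"conventional"`
#' @return numeric vector of returns
#' @export
kstep_return <- function(rewards, gammas, v_boot = 0, gamma_boot = 0,
                         form = c("as_printed", "conventional")) {
  form <- match.arg(form)
  T_len <- length(rewards)
  stopifnot(length(gammas) == T_len)
  g <- c(gammas, gamma_boot)
  out <- numeric(T_len)
  for (t in seq_len(T_len)) {
    k <- T_len - t + 1
    acc <- 0; prod <- 1
    for (i in 0:(k - 1)) {
      if (form == "as_printed") {
        prod <- prod * g[t + i]
        acc <- acc + rewards[t + i] * prod
      } else {
        acc <- acc + rewards[t + i] * prod
        prod <- prod * g[t + i]
      }
    }
    out[t] <- acc + v_boot * prod * (if (form == "as_printed")
      g[t + k] else 1)
  }
  out
}

#' Entropy of a policy
#'
#' @param p probability vector
#' @return `-sum(p log p)` (0 log 0 = 0)
#' @export
policy_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Advantage actor-critic losses and gradients for a fixed episode
#'
#' Scalar training losses over one recorded episode, with analytic
#' gradients: the critic loss `0.5 beta_v sum (R_t - V_t)^2` against
#' fixed target returns, and the actor loss
#' `sum(-log pi(a_t) A_t - beta_e H_t)` against fixed actions and
#' (detached) advantages. Exposed so gradient correctness can be checked
#' by finite differences.
#'
#' @param params network parameters (as from [init_dynamics_params()])
#' @param which `"critic"` or `"actor"`
#' @param X input matrix (input-dimension x steps)
#' @param returns target returns (critic)
#' @param actions 0-based action indices (actor)
#' @param advantages fixed advantages (actor)
#' @param beta_v,beta_e loss scaling factors
#' @return list with `loss` and gradient arrays
#' @export
a2c_loss <- function(params, which = c("critic", "actor"), X,
                     returns = NULL, actions = NULL, advantages = NULL,
                     beta_v = 0.05, beta_e = 0.05) {
  which <- match.arg(which)
  if (which == "critic")
    cs_critic_loss_grad(params, X, returns, beta_v)
  else
    cs_actor_loss_grad(params, X, as.integer(actions), advantages,
                       beta_e)
}

#' Train the actor-critic dynamics model
#'
#' Initializes both networks and trains them with A2C on the
#' geometric-reversal (p = 0.9) version of the task. Aborts with a
#' diagnostic if the loss diverges.
#'
#' @param config a [dynamics_config()]
#' @param seed RNG seed
#' @param params optional warm-start parameters
#' @return a `cs_dynamics_agent`: trained `params`, per-episode
#'   `learning_curve` (fraction of rewarded trials), `config`
#' @export
train_dynamics_model <- function(config = dynamics_config(), seed = 1L,
                                 params = NULL) {
  set.seed(seed)
  if (is.null(params)) params <- init_dynamics_params(config)
  res <- cs_a2c_train(params, dyn_cfg_cpp(config))
  structure(list(params = res$params,
                 learning_curve = as.numeric(res$curve),
                 reward_sum = as.numeric(res$reward_sum),
                 config = config, seed = seed),
            class = "cs_dynamics_agent")
}

#' @export
print.cs_dynamics_agent <- function(x, ...) {
  n <- length(x$learning_curve)
  tail_rate <- mean(x$learning_curve[max(1, n - 99):n])
  cat(sprintf(
    "<cs_dynamics_agent> %d units, %d episodes trained, final reward rate %.2f\n",
    x$config$n_units, n, tail_rate))
  invisible(x)
}

#' Test the dynamics model with frozen weights
#'
#' Behavior is generated purely by the trained networks' dynamics; no
#' weight changes occur. Episodes run on the reward-counted 70/10 task by
#' default, on fixed-length blocks for the geometry analyses, or on the
#' geometric rule.
#'
#' @param agent a `cs_dynamics_agent`
#' @param n_trials trials per episode (published testing uses 1500)
#' @param n_episodes number of test episodes
#' @param block `"reward_counted"`, `"geometric"` or `"fixed"`
#' @param fixed_len block length for `block = "fixed"`
#' @param stim_frac fraction of trials with dynamics-mode stimulation
#'   (70% of input neurons clamped to 0.15 for the whole trial)
#' @param record_h record the actor state at the decision step
#' @param seed RNG seed
#' @return list of per-episode results; each has a `session`
#'   (`cs_session`) plus `rpe02` (mean RPE 0-2 s post press) and
#'   optionally `h_decision`
#' @export
test_dynamics_model <- function(agent, n_trials = 1500L,
                                n_episodes = 1L,
                                block = c("reward_counted", "geometric",
                                          "fixed"),
                                fixed_len = 30L, stim_frac = 0,
                                record_h = FALSE, seed = 1L) {
  block <- match.arg(block)
  set.seed(seed)
  mode <- match(block, c("reward_counted", "geometric", "fixed")) - 1L
  mode <- c(0L, 1L, 2L)[mode + 1L]
  cfg <- dyn_cfg_cpp(agent$config)
  if (block == "geometric") cfg$geom_p <- agent$config$geom_p_train
  else cfg$geom_p <- 0.4
  lapply(seq_len(n_episodes), function(e) {
    res <- cs_a2c_run(agent$params, cfg, as.integer(n_trials), mode,
                      as.integer(fixed_len), stim_frac, 0.15, 0.7,
                      record_h)
    trials <- data.frame(
      trial = seq_len(n_trials),
      choice = c("left", "right", "none")[res$choice + 1L],
      outcome = res$outcome,
      block = c("left_high", "right_high")[res$block + 1L],
      stimulated = res$stimulated)
    out <- list(session = as_cs_session(trials, task_config()),
                rpe02 = res$rpe02)
    if (record_h) out$h_decision <- res$h_decision
    out
  })
}

#' Geometry of the actor network at the decision step
#'
#' Runs the frozen agent on fixed-length blocks, extracts the actor LSTM
#' state at the decision step of every trial, and summarizes: (i) the
#' principal components of that activity and their variance shares,
#' (ii) the cosine of the angle between the actor's decision readout axis
#' (left-minus-right readout weights) and each of the first components,
#' and (iii) a linear regression of the PC1 score on the previous
#' `n_back` trials' choice, RPE (0-2 s post-press average) and their
#' product.
#'
#' @param agent a `cs_dynamics_agent`
#' @param n_trials trials of the fixed-block test run
#' @param fixed_len block length (30)
#' @param n_back history depth of the PC1 regression (7)
#' @param n_pc number of components to report
#' @param seed RNG seed
#' @return list with `var_explained`, `cosines`, `pc1_regression` (data
#'   frame of lag, choice, rpe and interaction coefficients), `pc_scores`
#' @export
actor_geometry_analysis <- function(agent, n_trials = 900L,
                                    fixed_len = 30L, n_back = 7L,
                                    n_pc = 3L, seed = 1L) {
  run <- test_dynamics_model(agent, n_trials = n_trials, block = "fixed",
                             fixed_len = fixed_len, record_h = TRUE,
                             seed = seed)[[1]]
  H <- t(run$h_decision)                       # trials x units
  pc <- prcomp(H, center = TRUE, scale. = FALSE)
  var_exp <- pc$sdev^2 / sum(pc$sdev^2)
  w_dec <- agent$params$Wpi[1, ] - agent$params$Wpi[2, ]
  cosines <- vapply(seq_len(min(n_pc, ncol(pc$rotation))), function(k) {
    v <- pc$rotation[, k]
    if (sd(v) == 0 || sqrt(sum(w_dec^2)) == 0) return(NA_real_)
    sum(w_dec * v) / sqrt(sum(w_dec^2) * sum(v^2))
  }, numeric(1))
  pc1 <- pc$x[, 1]
  ch <- ifelse(run$session$choice == "left", 1,
               ifelse(run$session$choice == "right", -1, NA))
  rpe <- run$rpe02
  n <- length(pc1)
  idx <- (n_back + 1):n
  mk <- function(v) vapply(seq_len(n_back), function(j) v[idx - j],
                           numeric(length(idx)))
  Xc <- mk(ch); Xr <- mk(rpe); Xi <- mk(ch * rpe)
  colnames(Xc) <- paste0("choice", seq_len(n_back))
  colnames(Xr) <- paste0("rpe", seq_len(n_back))
  colnames(Xi) <- paste0("choice_x_rpe", seq_len(n_back))
  dat <- data.frame(pc1 = pc1[idx], Xc, Xr, Xi)
  fit <- lm(pc1 ~ ., data = dat, na.action = stats::na.omit)
  co <- coef(fit)
  reg <- data.frame(
    lag = seq_len(n_back),
    choice = unname(co[paste0("choice", seq_len(n_back))]),
    rpe = unname(co[paste0("rpe", seq_len(n_back))]),
    choice_x_rpe = unname(co[paste0("choice_x_rpe",
                                    seq_len(n_back))]))
  list(var_explained = var_exp, cosines = cosines, pc1_regression = reg,
       pc_scores = pc$x[, seq_len(min(n_pc, ncol(pc$x)))],
       session = run$session)
}
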