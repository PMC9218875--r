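# History-based logistic regressions of choice, the dopamine
# outcome-history regression, and stimulation-effect summaries.

# signed history regressors: R(i-j) is +1 for a rewarded right press,
# -1 for a rewarded left press, 0 if unrewarded j trials back (and
# symmetrically U for unrewarded presses)
history_design <- function(choice, outcome, stim = NULL, n_back = 5L) {
  n <- length(choice)
  signed <- ifelse(choice == "right", 1, -1)
  Rv <- signed * (outcome == 1)
  Uv <- signed * (outcome == 0)
  idx <- (n_back + 1):n
  lagmat <- function(v) vapply(seq_len(n_back), function(j) v[idx - j],
                               numeric(length(idx)))
  out <- list(y = as.integer(choice[idx] == "right"),
              R = lagmat(Rv), U = lagmat(Uv), idx = idx)
  if (!is.null(stim)) {
    Lv <- as.numeric(stim)
    out$L <- lagmat(Lv)
    out$LR <- lagmat(Lv * Rv)
    out$LU <- lagmat(Lv * Uv)
  }
  out
}

fit_logistic_flagged <- function(y, X) {
  df <- data.frame(y = y, X)
  fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)) > 15, na.rm = TRUE)
  if (sep) {
    # minimal ridge refit for stability under (quasi-)separation
    beta <- ridge_logistic(as.matrix(X), y, rep(1, length(y)),
                           lambda = 1e-3)
    co <- beta
    names(co) <- c("(Intercept)", colnames(X))
    se <- rep(NA_real_, length(co))
  } else {
    co <- coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
  }
  list(coef = co, se = se, ridged = sep)
}

#' Choice-history logistic regression
#'
#' Models the log-odds of a right-lever choice on trial i as a linear
#' function of signed rewarded-choice regressors R(i-j) and
#' unrewarded-choice regressors U(i-j) for lags j = 1..n_back. Positive
#' coefficients indicate a tendency to repeat (rewarded or unrewarded)
#' past choices. Abandoned trials are removed before lagging, so lags
#' count actual completed trials.
#'
#' @param session a `cs_session`
#' @param n_back number of history lags (default 5)
#' @return a `cs_choice_reg` list: `beta_R`, `beta_U` (length `n_back`),
#'   `intercept`, standard errors, `ridged` flag
#' @export
choice_history_regression <- function(session, n_back = 5L) {
  done <- session$choice != "none"
  choice <- session$choice[done]; outcome <- session$outcome[done]
  if (length(choice) < n_back + 10)
    stopf("need at least n_back + 10 completed trials")
  d <- history_design(choice, outcome, n_back = n_back)
  X <- cbind(d$R, d$U)
  colnames(X) <- c(paste0("R", seq_len(n_back)),
                   paste0("U", seq_len(n_back)))
  f <- fit_logistic_flagged(d$y, X)
  structure(list(beta_R = unname(f$coef[paste0("R", seq_len(n_back))]),
                 beta_U = unname(f$coef[paste0("U", seq_len(n_back))]),
                 intercept = unname(f$coef["(Intercept)"]),
                 se = f$se, coef = f$coef, ridged = f$ridged,
                 n_back = n_back),
            class = "cs_choice_reg")
}

#' Choice-history regression with stimulation terms
#'
#' Extends [choice_history_regression()] with stimulation main effects
#' L(i-j) and the rewarded-choice x stimulation and unrewarded-choice x
#' stimulation interactions. The combined traces `beta_R + beta_LR` and
#' `beta_U + beta_LU` give the effective influence of previously
#' stimulated rewarded/unrewarded choices.
#'
#' @inheritParams choice_history_regression
#' @return a `cs_stim_choice_reg` list adding `beta_L`, `beta_LR`,
#'   `beta_LU`, `combined_R`, `combined_U`
#' @export
stim_choice_regression <- function(session, n_back = 5L) {
  done <- session$choice != "none"
  choice <- session$choice[done]; outcome <- session$outcome[done]
  stim <- session$stimulated[done]
  if (!any(stim)) stopf("no stimulated trials: interaction terms undefined")
  if (length(choice) < n_back + 10)
    stopf("need at least n_back + 10 completed trials")
  d <- history_design(choice, outcome, stim, n_back = n_back)
  X <- cbind(d$R, d$U, d$LR, d$LU, d$L)
  colnames(X) <- c(paste0("R", seq_len(n_back)),
                   paste0("U", seq_len(n_back)),
                   paste0("LR", seq_len(n_back)),
                   paste0("LU", seq_len(n_back)),
                   paste0("L", seq_len(n_back)))
  f <- fit_logistic_flagged(d$y, X)
  g <- function(p) unname(f$coef[paste0(p, seq_len(n_back))])
  structure(list(beta_R = g("R"), beta_U = g("U"), beta_LR = g("LR"),
                 beta_LU = g("LU"), beta_L = g("L"),
                 combined_R = g("R") + g("LR"),
                 combined_U = g("U") + g("LU"),
                 intercept = unname(f$coef["(Intercept)"]),
                 se = f$se, coef = f$coef, ridged = f$ridged,
                 n_back = n_back),
            class = "cs_stim_choice_reg")
}

#' Outcome-history regression of dopamine (RPE) activity
#'
#' Linear regression of the per-trial average dopamine response in the
#' feedback window (0.2-1.2 s after reward feedback) on the outcome of the
#' current and previous `n_back` trials. In the circuit models the
#' dependent variable is the window-averaged simulated RPE.
#'
#' @param rpe_by_trial per-trial window-averaged dopamine/RPE values
#' @param outcomes per-trial outcomes (0/1), same length
#' @param n_back history depth (default 5)
#' @return a `cs_da_reg` list: `beta` (named lag0..lag`n_back`),
#'   `intercept`, `se`
#' @export
dopamine_history_regression <- function(rpe_by_trial, outcomes,
                                        n_back = 5L) {
  n <- length(rpe_by_trial)
  if (length(outcomes) != n) stopf("length mismatch")
  if (n < n_back + 10) stopf("need at least n_back + 10 trials")
  idx <- (n_back + 1):n
  X <- vapply(0:n_back, function(j) outcomes[idx - j],
              numeric(length(idx)))
  colnames(X) <- paste0("lag", 0:n_back)
  fit <- lm(rpe_by_trial[idx] ~ X)
  co <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  beta <- co[-1]; names(beta) <- colnames(X)
  structure(list(beta = beta, intercept = unname(co[1]), se = se,
                 n_back = n_back),
            class = "cs_da_reg")
}
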