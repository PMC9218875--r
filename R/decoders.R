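# Sequence-type-weighted logistic decoding of choice and outcome, and the
# piecewise trial time warp with binned time-course decoding.

#' Decoder specification
#'
#' @param ensemble_size neurons per random ensemble (1-10)
#' @param n_resamples random ensembles to average over (default 100)
#' @param cv_folds cross-validation folds (default 5)
#' @param threshold decision threshold on the predicted probability
#' @param ridge minimal ridge penalty for numerical stability under
#'   separation
#' @export
decoder_spec <- function(ensemble_size = 10L, n_resamples = 100L,
                         cv_folds = 5L, threshold = 0.5, ridge = 1e-6) {
  structure(list(ensemble_size = as.integer(ensemble_size),
                 n_resamples = as.integer(n_resamples),
                 cv_folds = as.integer(cv_folds), threshold = threshold,
                 ridge = ridge),
            class = "cs_decoder_spec")
}

#' Inverse-frequency sequence-type trial weights
#'
#' Choices (and outcomes) are autocorrelated across neighbouring trials,
#' so an unweighted decoder can exploit the previous or next trial's label.
#' Each trial is classified into one of eight previous-current-future
#' label triplets and weighted by the inverse of its triplet's frequency,
#' equalizing the triplets' influence. The first and last trials cannot be
#' classified and receive `NA`.
#'
#' @param labels per-trial labels (two levels; e.g. choice side or outcome)
#' @return numeric vector of weights (NA for unclassifiable trials)
#' @export
sequence_type_weights <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  type <- rep(NA_character_, n)
  if (n >= 3) {
    idx <- 2:(n - 1)
    type[idx] <- paste(labels[idx - 1], labels[idx], labels[idx + 1],
                       sep = "-")
  }
  counts <- table(type)
  w <- rep(NA_real_, n)
  ok <- !is.na(type)
  w[ok] <- 1 / as.numeric(counts[type[ok]])
  w
}

# weighted ridge logistic fit (IRLS on the penalized likelihood); the tiny
# default penalty only guards against separation
ridge_logistic <- function(X, y, w, lambda = 1e-6, maxit = 50) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  for (it in seq_len(maxit)) {
    eta <- drop(X1 %*% beta)
    mu <- 1 / (1 + exp(-pmin(pmax(eta, -30), 30)))
    wt <- w * mu * (1 - mu)
    wt <- pmax(wt, 1e-10)
    z <- eta + (y - mu) / (mu * (1 - mu) + 1e-10)
    H <- crossprod(X1, X1 * wt) + pen
    beta_new <- tryCatch(solve(H, crossprod(X1, wt * z)),
                         error = function(e) beta)
    if (max(abs(beta_new - beta)) < 1e-8) { beta <- beta_new; break }
    beta <- beta_new
  }
  drop(beta)
}

#' Decode binary labels from trial features
#'
#' Weighted logistic decoding: for each of `n_resamples` random ensembles
#' of `ensemble_size` neurons, fits a sequence-type-weighted logistic
#' regression with `cv_folds`-fold cross-validation and classifies
#' held-out trials at the probability threshold. Returns the accuracy
#' (unweighted fraction of correctly classified held-out trials) averaged
#' over ensembles and folds.
#'
#' @param features trials x neurons matrix (e.g. mean activity in the
#'   decoding window)
#' @param labels per-trial binary labels (factor or character)
#' @param spec a [decoder_spec()]
#' @param weights optional per-trial weights; by default the
#'   [sequence_type_weights()] of `labels`. Trials with `NA` weight are
#'   excluded.
#' @return list with `accuracy`, `per_resample` accuracies, `n_trials`
#' @export
decode_labels <- function(features, labels, spec = decoder_spec(),
                          weights = NULL) {
  features <- as.matrix(features)
  if (is.null(weights)) weights <- sequence_type_weights(labels)
  keep <- !is.na(weights) & !is.na(labels)
  features <- features[keep, , drop = FALSE]
  y <- as.integer(factor(as.character(labels[keep]))) - 1L
  w <- weights[keep]
  n <- length(y)
  if (ncol(features) < spec$ensemble_size)
    stopf("need at least %d neurons", spec$ensemble_size)
  acc <- numeric(spec$n_resamples)
  for (r in seq_len(spec$n_resamples)) {
    sel <- sample.int(ncol(features), spec$ensemble_size)
    folds <- sample(rep_len(seq_len(spec$cv_folds), n))
    correct <- logical(n)
    for (f in seq_len(spec$cv_folds)) {
      tr <- folds != f
      beta <- ridge_logistic(features[tr, sel, drop = FALSE], y[tr],
                             w[tr], spec$ridge)
      eta <- drop(cbind(1, features[!tr, sel, drop = FALSE]) %*% beta)
      pred <- as.integer(1 / (1 + exp(-eta)) >= spec$threshold)
      correct[!tr] <- pred == y[!tr]
    }
    acc[r] <- mean(correct)
  }
  list(accuracy = mean(acc), per_resample = acc, n_trials = n)
}

#' Mean-activity decoding features from population activity trials
#'
#' @param trials list of `cs_pop_activity`
#' @param window seconds relative to the press over which to average
#' @return trials x neurons feature matrix
#' @export
activity_features <- function(trials, window = c(-2, 6)) {
  t(vapply(trials, function(tr) {
    cols <- tr$time >= window[1] & tr$time <= window[2]
    rowMeans(tr$rates[, cols, drop = FALSE])
  }, numeric(nrow(trials[[1]]$rates))))
}

#' Piecewise-linear trial time warping onto a common grid
#'
#' Removes trial-to-trial timing variability by mapping each trial onto an
#' adjusted clock anchored at the nose poke, lever press and the next
#' trial's nose poke: the 2 s before the nose poke and the 3 s after the
#' next nose poke pass through unwarped, while the nose-poke-to-press and
#' press-to-next-nose-poke epochs are linearly rescaled to their
#' across-trial median durations. The adjusted time is continuous at the
#' anchors. Trials with non-monotone anchors are dropped and reported.
#'
#' @param traces time x neurons matrix of the session trace
#' @param time absolute time of each sample, seconds
#' @param anchors data frame with per-trial absolute `nose_poke`,
#'   `lever_press`, `next_nose_poke` times
#' @param rate output sampling rate, Hz
#' @return list with `warped` (trials x adjusted-time x neurons array),
#'   `adj_time` (adjusted clock, 0 at the nose poke), `median_epochs`,
#'   `dropped` (indices of dropped trials)
#' @export
time_warp_trials <- function(traces, time, anchors, rate = 10) {
  traces <- as.matrix(traces)
  mono <- with(anchors, nose_poke < lever_press &
                 lever_press < next_nose_poke)
  dropped <- which(!mono | is.na(mono))
  keep <- setdiff(seq_len(nrow(anchors)), dropped)
  m2 <- stats::median(anchors$lever_press[keep] - anchors$nose_poke[keep])
  m3 <- stats::median(anchors$next_nose_poke[keep] -
                        anchors$lever_press[keep])
  adj_time <- seq(-2, m2 + m3 + 3, by = 1 / rate)
  n_nrn <- ncol(traces)
  warped <- array(NA_real_, c(length(keep), length(adj_time), n_nrn))
  for (ti in seq_along(keep)) {
    tr <- keep[ti]
    np <- anchors$nose_poke[tr]; lp <- anchors$lever_press[tr]
    np2 <- anchors$next_nose_poke[tr]
    # invert the adjusted clock back to original time
    orig <- ifelse(adj_time < 0, np + adj_time,
            ifelse(adj_time < m2, np + adj_time / m2 * (lp - np),
            ifelse(adj_time < m2 + m3,
                   lp + (adj_time - m2) / m3 * (np2 - lp),
                   np2 + adj_time - m2 - m3)))
    for (j in seq_len(n_nrn))
      warped[ti, , j] <- approx(time, traces[, j], xout = orig,
                                rule = 2)$y
  }
  list(warped = warped, adj_time = adj_time,
       median_epochs = c(ii = m2, iii = m3), dropped = dropped,
       kept = keep)
}

#' Binned time-course decoding on warped trials
#'
#' Decodes the label of the trial at `lag` (0 = current, -1 = previous,
#' +1 = next, -2 = two back) from each 500 ms bin of the warped traces,
#' using the sequence-type-weighted decoder.
#'
#' @param warp result of [time_warp_trials()]
#' @param labels per-trial labels aligned to the *original* trial indices
#' @param lag trial lag of the decoded label
#' @param spec a [decoder_spec()]
#' @param bin bin width, seconds
#' @return data frame with `bin_start`, `bin_mid`, `accuracy`
#' @export
timecourse_decoding <- function(warp, labels, lag = 0L,
                                spec = decoder_spec(), bin = 0.5) {
  labels <- as.character(labels)
  n_all <- length(labels)
  w_all <- sequence_type_weights(labels)
  kept <- warp$kept
  lab_idx <- kept + lag
  ok <- lab_idx >= 1 & lab_idx <= n_all
  lagged <- rep(NA_character_, length(kept))
  lagged[ok] <- labels[lab_idx[ok]]
  wts <- rep(NA_real_, length(kept))
  wts[ok] <- w_all[kept[ok]]
  edges <- seq(warp$adj_time[1], max(warp$adj_time) - bin + 1e-9, by = bin)
  if (!length(edges)) stopf("bins extend beyond the warped grid")
  res <- lapply(edges, function(b0) {
    cols <- warp$adj_time >= b0 & warp$adj_time < b0 + bin
    feats <- apply(warp$warped[, cols, , drop = FALSE], c(1, 3), mean)
    out <- decode_labels(feats, lagged, spec, weights = wts)
    data.frame(bin_start = b0, bin_mid = b0 + bin / 2,
               accuracy = out$accuracy)
  })
  do.call(rbind, res)
}

#' Across-session test of decoding accuracy against chance
#'
#' Two-tailed one-sample t-test of per-session accuracies against 0.5.
#'
#' @param accuracies numeric vector of per-session accuracies
#' @return htest object
#' @export
decoding_vs_chance <- function(accuracies) {
  stats::t.test(accuracies, mu = 0.5)
}
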