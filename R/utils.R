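#' @useDynLib creditseq, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef dnorm glm lm lm.fit pnorm prcomp qnorm
#'   rbinom rgeom rnorm runif sd var binomial cor predict quantile
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Draw from a normal distribution truncated below at zero
#'
#' Inverse-CDF sampling from `N(mean, sd)` conditioned on being
#' non-negative. Used for the probe input of the plasticity model's action
#' readout and for multiplicative amplitude noise of the sequence generator,
#' both of which are non-negative rates.
#'
#' @param n number of draws
#' @param mean,sd parameters of the untruncated normal
#' @return numeric vector of non-negative draws
#' @export
rtnorm0 <- function(n, mean, sd) {
  if (sd <= 0) return(rep(pmax(mean, 0), length.out = n))
  p0 <- pnorm(0, mean, sd)
  u <- runif(n, p0, 1)
  qnorm(u, mean, sd)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 1 && x == floor(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x <= 1
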