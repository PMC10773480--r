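#' Mean-dispersion parameter set for the beta-binomial distribution
#'
#' Constructs and validates the `(p, theta, n)` triple used throughout the
#' package.  The number of successes in `n` trials is beta-binomial when the
#' per-trial success probability is itself drawn from a Beta distribution;
#' here that Beta is parametrized by its mean `p` and a dispersion (inverse
#' variability) parameter `theta`, with shape parameters
#' `alpha = p * theta` and `beta = (1 - p) * theta`.  Under this convention
#' `p = 0.5, theta = 2` gives the uniform distribution of underlying
#' probabilities, so the count is discrete-uniform on `0..n`.  Smaller
#' `theta` means a more dispersed probability distribution (greater
#' intraindividual variability when used longitudinally); as `theta` grows
#' the distribution approaches the ordinary binomial.
#'
#' The mean parameter is sometimes written \eqn{\mu} and the dispersion
#' \eqn{\phi}, \eqn{\kappa} or \eqn{\rho} elsewhere; code in this package
#' always uses `p` and `theta`.
#'
#' @param p average probability, in the open interval (0, 1).
#' @param theta positive dispersion parameter of the underlying beta
#'   distribution (low `theta` = high variability).
#' @param n_trials number of Bernoulli trials per observation (default 20,
#'   the two-phase 10-word recall test).
#' @return An object of class `"bb_params"`: a list with elements `p`,
#'   `theta`, `n_trials`.
#' @examples
#' bb_params(0.5, 2)            # uniform underlying probabilities
#' bb_shapes(bb_params(0.25, 8))  # alpha = 2, beta = 6
#' @export
bb_params <- function(p, theta, n_trials = 20L) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(theta) || any(!is.finite(theta)) || any(theta <= 0))
    stop("`theta` must be a positive real", call. = FALSE)
  if (any(n_trials < 1) || any(n_trials != as.integer(n_trials)))
    stop("`n_trials` must be a positive integer", call. = FALSE)
  structure(list(p = p, theta = theta, n_trials = as.integer(n_trials)),
            class = "bb_params")
}

#' Convert mean-dispersion parameters to beta shape parameters
#'
#' @param params a [bb_params()] object.
#' @return Named numeric vector (or matrix for vector input) with elements
#'   `alpha = p * theta` and `beta = (1 - p) * theta`.  The implied beta
#'   distribution has mean `alpha / (alpha + beta) = p`.
#' @export
bb_shapes <- function(params) {
  stopifnot(inherits(params, "bb_params"))
  c(alpha = params$p * params$theta, beta = (1 - params$p) * params$theta)
}

# Internal vectorized log-pmf on the (p, theta) scale; all work in log-gamma
# space, no factorials.  theta is clamped to [1e-8, 1e12] to avoid overflow
# in lgamma; clamping events are counted in the "melsbb.theta.clamped"
# option so likelihood code can report them.
bb_lpmf <- function(y, p, theta, n) {
  lo <- theta < 1e-8
  hi <- theta > 1e12
  if (any(lo | hi)) {
    theta <- pmin(pmax(theta, 1e-8), 1e12)
    prev <- getOption("melsbb.theta.clamped", 0L)
    options(melsbb.theta.clamped = prev + sum(lo | hi))
  }
  a <- p * theta
  b <- (1 - p) * theta
  lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b)
}

#' Beta-binomial log probability mass
#'
#' Computes `log P(Y = y)` for the count `Y` of successes in `n` trials with
#' beta-distributed success probability,
#' `P(Y = y) = C(n, y) B(y + alpha, n - y + beta) / B(alpha, beta)`,
#' evaluated entirely via log-gamma for numerical stability.
#'
#' @param y integer count(s) in `0..n_trials`.
#' @param params a [bb_params()] object.
#' @return Log probability, finite for all valid inputs.
#' @export
bb_log_pmf <- function(y, params) {
  stopifnot(inherits(params, "bb_params"))
  if (any(y < 0) || any(y > params$n_trials) || any(y != as.integer(y)))
    stop("`y` must be an integer in [0, n_trials]", call. = FALSE)
  bb_lpmf(y, params$p, params$theta, params$n_trials)
}

#' Brute-force beta-binomial probability via adaptive quadrature
#'
#' Independent verification oracle: evaluates
#' \deqn{\int_0^1 C(n,y)\, \pi^y (1-\pi)^{n-y}\, f_{Beta}(\pi; \alpha, \beta)\, d\pi}
#' by adaptive numerical integration rather than the closed form used by
#' [bb_log_pmf()].  Intended for testing; accuracy about 1e-10.
#'
#' @inheritParams bb_log_pmf
#' @return Probability on the natural scale.
#' @details The integral is evaluated on the logit scale,
#'   `pi = plogis(s)`, whose Jacobian `pi (1 - pi)` removes the endpoint
#'   singularities of U-shaped betas (`alpha < 1` or `beta < 1`) so the
#'   adaptive quadrature converges for every valid parameter set.
#' @export
bb_pmf_oracle <- function(y, params) {
  stopifnot(inherits(params, "bb_params"))
  if (any(y < 0) || any(y > params$n_trials))
    stop("`y` must be an integer in [0, n_trials]", call. = FALSE)
  sh <- bb_shapes(params)
  n <- params$n_trials
  a <- sh[["alpha"]]; b <- sh[["beta"]]
  vapply(y, function(yy) {
    integrand <- function(s) {
      # log pi and log(1 - pi) directly from the logit, stable at +/-Inf
      lp <- stats::plogis(s, log.p = TRUE)
      lq <- stats::plogis(-s, log.p = TRUE)
      exp(lchoose(n, yy) - lbeta(a, b) +
            (yy + a) * lp + (n - yy + b) * lq)
    }
    stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-12,
                     abs.tol = 1e-13, subdivisions = 1000L)$value
  }, numeric(1))
}

#' Mean and variance of the beta-binomial distribution
#'
#' `mean = n p` and `variance = n p (1 - p) (theta + n) / (theta + 1)`.
#' The variance is strictly decreasing in `theta` at fixed `(n, p)`:
#' low dispersion-parameter values imply greater variability, and as
#' `theta` grows the variance approaches the binomial `n p (1 - p)`.
#'
#' @param params a [bb_params()] object.
#' @return Named numeric vector `c(mean, variance)`.
#' @export
bb_moments <- function(params) {
  stopifnot(inherits(params, "bb_params"))
  n <- params$n_trials; p <- params$p; th <- params$theta
  c(mean = n * p,
    variance = n * p * (1 - p) * (th + n) / (th + 1))
}

#' Sample beta-binomial counts
#'
#' Two-stage draw mirroring the generative description of the model: a
#' probability is drawn from the underlying beta distribution for each
#' observation, then the count from a binomial at that probability.
#'
#' @param params a [bb_params()] object.
#' @param count number of independent scores to draw.
#' @param seed integer RNG seed; the draw is reproducible given the seed.
#'   `NULL` continues the current RNG stream.
#' @return Integer vector of length `count`, each value in `0..n_trials`.
#' @export
bb_sample <- function(params, count, seed = NULL) {
  stopifnot(inherits(params, "bb_params"))
  if (length(count) != 1L || count < 1 || count != as.integer(count))
    stop("`count` must be a positive integer", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sh <- bb_shapes(params)
  pi_ <- stats::rbeta(count, sh[["alpha"]], sh[["beta"]])
  stats::rbinom(count, params$n_trials, pi_)
}

# Vectorized two-stage sampler on raw (p, theta) vectors; used by the
# model simulator where every observation has its own parameters.
bb_sample_vec <- function(p, theta, n) {
  pi_ <- stats::rbeta(length(p), p * theta, (1 - p) * theta)
  stats::rbinom(length(p), n, pi_)
}

#' Predicted score distribution over 0..n
#'
#' Exact pmf of the beta-binomial at given `(p, theta, n)`; the building
#' block for plotting expected test-score distributions under different
#' amounts of intraindividual variability (a flat line at `1/(n+1)` when
#' `p = 0.5, theta = 2`; concentrated around the mean for large `theta`;
#' mass pushed to the extremes for `theta < 2`).
#'
#' @param p average probability.
#' @param theta dispersion parameter.
#' @param n_trials number of trials.
#' @return Data frame with columns `score` (0..n) and `prob`, summing to 1.
#' @export
predicted_score_distribution <- function(p, theta, n_trials = 20L) {
  pars <- bb_params(p, theta, n_trials)
  data.frame(score = 0:n_trials,
             prob = exp(bb_log_pmf(0:n_trials, pars)))
}
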