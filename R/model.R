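#' Fixed-effect coefficient set
#'
#' @param beta_p named numeric vector aligned to the columns of `X_p`
#'   (logit scale for the average probability).
#' @param beta_theta named numeric vector aligned to `X_theta` (log scale
#'   for the dispersion).
#' @return Object of class `"mels_fixef"`.
#' @export
mels_fixef <- function(beta_p, beta_theta) {
  stopifnot(all(is.finite(beta_p)), all(is.finite(beta_theta)))
  structure(list(beta_p = beta_p, beta_theta = beta_theta),
            class = "mels_fixef")
}

#' Random-effect covariance specification
#'
#' The three person-level effects are: `u0`, the intercept deviation of the
#' logit average probability at the reference age; `u1`, the deviation of
#' the linear age slope (per decade) of that logit; and `v0`, the intercept
#' deviation of the log dispersion.  They are jointly trivariate normal
#' with zero mean, standard deviations `(sd_u0, sd_u1, sd_v0)` and a free
#' correlation matrix.
#'
#' @param sd_u0,sd_u1,sd_v0 positive standard deviations.
#' @param corr 3x3 correlation matrix (symmetric, unit diagonal, positive
#'   definite), ordered (u0, u1, v0).
#' @return Object of class `"mels_ranef"`.
#' @export
mels_ranef <- function(sd_u0, sd_u1, sd_v0, corr = diag(3)) {
  sds <- c(sd_u0, sd_u1, sd_v0)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("random-effect SDs must be non-negative", call. = FALSE)
  corr <- unname(as.matrix(corr))
  if (!isTRUE(all.equal(corr, t(corr), tolerance = 1e-10)) ||
      !isTRUE(all.equal(diag(corr), rep(1, 3), tolerance = 1e-10)))
    stop("`corr` must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("`corr` must be positive definite", call. = FALSE)
  structure(list(sd = stats::setNames(sds, c("u0", "u1", "v0")), corr = corr),
            class = "mels_ranef")
}

#' Prior settings
#'
#' Weakly-informative defaults: normal(0, 5) on the two intercepts,
#' normal(0, 2.5) on every other fixed effect, half-Student-t(3, 0, 2.5) on
#' the random-effect SDs, and an LKJ(eta) prior on the correlation matrix
#' (eta = 1 is uniform over valid correlation matrices).
#'
#' @param intercept_scale,slope_scale normal prior SDs for fixed effects.
#' @param sd_df,sd_scale half-t parameters for the random-effect SDs.
#' @param lkj_eta LKJ concentration.
#' @return Object of class `"mels_priors"`.
#' @export
mels_priors <- function(intercept_scale = 5, slope_scale = 2.5,
                        sd_df = 3, sd_scale = 2.5, lkj_eta = 1) {
  stopifnot(intercept_scale > 0, slope_scale > 0, sd_df > 0, sd_scale > 0,
            lkj_eta > 0)
  structure(list(intercept_scale = intercept_scale,
                 slope_scale = slope_scale,
                 sd_df = sd_df, sd_scale = sd_scale, lkj_eta = lkj_eta),
            class = "mels_priors")
}

#' Linear predictor for the average probability
#'
#' `logit(p) = x' beta_p + u0 + u1 * z_age`; the random slope term
#' vanishes at the reference (centring) age where `z_age = 0`.
#'
#' @param x design row(s) of `X_p` (vector or matrix).
#' @param fe a [mels_fixef()].
#' @param u0,u1 person intercept and age-slope deviations.
#' @param z_age centred age in decades.
#' @return Logit-scale linear predictor; apply `plogis()` for `p`.
#' @export
linear_predictor_p <- function(x, fe, u0 = 0, u1 = 0, z_age = 0) {
  x <- rbind(x, deparse.level = 0L)
  if (ncol(x) != length(fe$beta_p))
    stop("design/coefficient dimension mismatch in p-predictor",
         call. = FALSE)
  drop(x %*% fe$beta_p) + u0 + u1 * z_age
}

#' Linear predictor for the dispersion
#'
#' `log(theta) = w' beta_theta + v0`; negative person effects `v0` lower
#' the dispersion parameter and therefore raise the score variance.
#'
#' @param w design row(s) of `X_theta`.
#' @param fe a [mels_fixef()].
#' @param v0 person dispersion-intercept deviation.
#' @return Log-scale linear predictor; apply `exp()` for `theta`.
#' @export
linear_predictor_theta <- function(w, fe, v0 = 0) {
  w <- rbind(w, deparse.level = 0L)
  if (ncol(w) != length(fe$beta_theta))
    stop("design/coefficient dimension mismatch in theta-predictor",
         call. = FALSE)
  drop(w %*% fe$beta_theta) + v0
}

# Linear predictors are clamped before the inverse links: log-theta at
# +/- 16 (beyond which the count is numerically binomial/Bernoulli-mix
# and lgamma differences would lose precision), logit-p at +/- 15 (so p
# never rounds to exactly 0 or 1).  Both are inactive at any plausible
# parameter values.
LOG_THETA_CLAMP <- 16
LOGIT_P_CLAMP <- 15

# Per-observation (p, theta) given design + parameters; effects is an
# n_persons x 3 matrix of (u0, u1, v0).
mels_obs_params <- function(design, fe, effects) {
  pi_ <- design$person_index
  eta_p <- drop(design$X_p %*% fe$beta_p) +
    effects[pi_, 1L] + effects[pi_, 2L] * design$z_age
  eta_p <- pmin(pmax(eta_p, -LOGIT_P_CLAMP), LOGIT_P_CLAMP)
  eta_t <- drop(design$X_theta %*% fe$beta_theta) + effects[pi_, 3L]
  eta_t <- pmin(pmax(eta_t, -LOG_THETA_CLAMP), LOG_THETA_CLAMP)
  list(p = stats::plogis(eta_p), theta = exp(eta_t))
}

# Trivariate-normal log density of the rows of `effects` under a
# mels_ranef specification.
ranef_log_density <- function(effects, re) {
  Sigma <- diag(re$sd) %*% re$corr %*% diag(re$sd)
  L <- chol(Sigma)
  z <- backsolve(L, t(effects), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(L))) - 1.5 * log(2 * pi)
}

# Log prior density of all parameters (up to additive constants that do
# not depend on the parameters).
prior_log_density <- function(fe, re, priors, intercept_idx_p = 1L,
                              intercept_idx_theta = 1L) {
  sc_p <- rep(priors$slope_scale, length(fe$beta_p))
  sc_p[intercept_idx_p] <- priors$intercept_scale
  sc_t <- rep(priors$slope_scale, length(fe$beta_theta))
  sc_t[intercept_idx_theta] <- priors$intercept_scale
  lp <- sum(stats::dnorm(fe$beta_p, 0, sc_p, log = TRUE)) +
    sum(stats::dnorm(fe$beta_theta, 0, sc_t, log = TRUE))
  # half-t(df, 0, scale) on each SD
  lp <- lp + sum(stats::dt(re$sd / priors$sd_scale, priors$sd_df,
                           log = TRUE) - log(priors$sd_scale) + log(2))
  # LKJ(eta) density on the correlation matrix, up to its normalizing
  # constant: (eta - 1) * log det(R); zero when eta = 1.
  lp + (priors$lkj_eta - 1) * determinant(re$corr)$modulus[1]
}

#' Joint log posterior density of the location-scale beta-binomial model
#'
#' Sum of (i) the beta-binomial log pmf of every observation at its
#' person-and-wave-specific `(p, theta)`, (ii) the trivariate-normal log
#' density of every person's random-effect triple, and (iii) the log prior
#' density of the fixed effects, random-effect SDs and correlation matrix.
#'
#' @param design a [build_design()] result.
#' @param fe a [mels_fixef()] aligned to the design.
#' @param re a [mels_ranef()].
#' @param effects numeric matrix, one row per person, columns (u0, u1, v0).
#' @param priors a [mels_priors()], or `NULL` to omit the prior term.
#' @return Scalar log density (finite at any interior point).
#' @export
joint_log_density <- function(design, fe, re, effects, priors = mels_priors()) {
  stopifnot(inherits(design, "mels_design"))
  if (nrow(effects) != length(design$person_ids) || ncol(effects) != 3L)
    stop("`effects` must be n_persons x 3", call. = FALSE)
  ob <- mels_obs_params(design, fe, effects)
  ll <- sum(bb_lpmf(design$y, ob$p, ob$theta, design$n_trials))
  lr <- sum(ranef_log_density(effects, re))
  lp <- if (is.null(priors)) 0 else prior_log_density(fe, re, priors)
  ll + lr + lp
}

#' Observation-level log-likelihood for each posterior draw
#'
#' Conditional on each draw's sampled person effects (the observation-level
#' convention needed for PSIS-LOO on hierarchical models), returns the
#' matrix of beta-binomial log pmfs.
#'
#' @param draws a `mels_draws` object (see [fit_mcmc()] /
#'   [draws_from_laplace()]); must carry person effects.
#' @param design the [build_design()] the draws were fitted to.
#' @return Matrix of dimension (n_draws, n_obs); row `s` sums to the data
#'   term of [joint_log_density()] at draw `s`.
#' @export
pointwise_loglik <- function(draws, design) {
  if (is.null(draws$effects))
    stop("draws do not carry person effects", call. = FALSE)
  S <- nrow(draws$beta_p)
  out <- matrix(NA_real_, S, length(design$y))
  for (s in seq_len(S)) {
    fe <- mels_fixef(draws$beta_p[s, ], draws$beta_theta[s, ])
    ob <- mels_obs_params(design, fe, draws$effects[s, , ])
    out[s, ] <- bb_lpmf(design$y, ob$p, ob$theta, design$n_trials)
  }
  out
}

#' Simulate scores from the generative model
#'
#' Draws each person's random-effect triple from the trivariate normal,
#' forms `(p, theta)` per observation, and samples scores through the
#' two-stage beta-then-binomial construction.
#'
#' @param design a [build_design()] result providing covariates and rows.
#' @param fe,re truth parameters ([mels_fixef()], [mels_ranef()]).
#' @param seed integer seed; `NULL` continues the RNG stream.
#' @return List with integer vector `scores` (aligned to design rows) and
#'   matrix `effects` (n_persons x 3) of the sampled latent effects.
#' @export
simulate_from_model <- function(design, fe, re, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_persons <- length(design$person_ids)
  Sigma <- diag(re$sd) %*% re$corr %*% diag(re$sd)
  Lt <- chol(Sigma)                     # upper triangular, Sigma = Lt'Lt
  effects <- matrix(stats::rnorm(n_persons * 3L), n_persons, 3L) %*% Lt
  ob <- mels_obs_params(design, fe, effects)
  scores <- bb_sample_vec(ob$p, ob$theta, design$n_trials)
  list(scores = scores, effects = effects)
}
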