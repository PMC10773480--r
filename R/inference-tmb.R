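#' @keywords internal
"_PACKAGE"

#' @useDynLib melsbb, .registration = TRUE
#' @importFrom TMB MakeADFun sdreport
NULL

# Shared assembly of the TMB data list from a design + priors.
tmb_data <- function(design, priors, include_prior = TRUE) {
  list(
    Xp = unname(design$X_p), Xt = unname(design$X_theta),
    zage = design$z_age, y = as.numeric(design$y),
    ntr = as.numeric(design$n_trials) + numeric(length(design$y)),
    lchoose_ny = lchoose(design$n_trials, design$y) +
      numeric(length(design$y)),
    person = design$person_index - 1L,
    prior_sc_p = prior_scales(colnames(design$X_p), priors),
    prior_sc_t = prior_scales(colnames(design$X_theta), priors),
    sd_df = priors$sd_df, sd_scale = priors$sd_scale,
    lkj_eta = priors$lkj_eta,
    include_prior = as.integer(include_prior)
  )
}

prior_scales <- function(cols, priors) {
  sc <- rep(priors$slope_scale, length(cols))
  sc[cols == "intercept"] <- priors$intercept_scale
  sc
}

# Correlation Cholesky factor from canonical partial correlations
# (z21, z31, z32); mirrors the compiled template.
cpc_chol <- function(z) {
  L <- diag(3)
  L[2, 1] <- z[1]; L[2, 2] <- sqrt(1 - z[1]^2)
  L[3, 1] <- z[2]
  L[3, 2] <- z[3] * sqrt(1 - z[2]^2)
  L[3, 3] <- sqrt(max(1 - L[3, 1]^2 - L[3, 2]^2, 1e-12))
  L
}

cpc_corrs <- function(z) {
  L <- cpc_chol(z)
  R <- L %*% t(L)
  c(r_u0_u1 = R[2, 1], r_u0_v0 = R[3, 1], r_u1_v0 = R[3, 2])
}

#' Fit the model by posterior mode with Laplace-integrated person effects
#'
#' Maximizes the log posterior of the fixed effects, random-effect SDs and
#' correlation parameters, with the person-level effects integrated out by
#' the Laplace approximation (automatic differentiation through TMB).
#' Deterministic given the data: no Monte Carlo anywhere.  Standard errors
#' come from the curvature (inverse Hessian) at the mode, delta-method
#' transformed for SDs and correlations.
#'
#' @param panel long-format panel data frame, or a prebuilt
#'   [build_design()] object.
#' @param spec a [mels_spec()]; ignored when `panel` is already a design.
#' @param priors a [mels_priors()].
#' @param permissive if `FALSE` (default) an optimizer that fails to
#'   converge is an error carrying the optimizer message; if `TRUE` the
#'   fit is returned with a warning.
#' @param verbose print optimizer progress.
#' @return Object of class `"mels_fit"`: list with `estimates` (named
#'   list: `beta_p`, `beta_theta`, `sd`, `corr`), `se` (same structure),
#'   `cov_fixed` (covariance of the internal parameter vector),
#'   `effects` (conditional modes of the person effects, n_persons x 3),
#'   `design`, `objective` (negative log posterior at the mode),
#'   `convergence` and `message`.
#' @export
fit_map_laplace <- function(panel, spec = mels_spec(),
                            priors = mels_priors(),
                            permissive = FALSE, verbose = FALSE) {
  design <- if (inherits(panel, "mels_design")) panel
            else build_design(panel, spec)
  np <- length(design$person_ids)
  dat <- tmb_data(design, priors)
  # warm start: crude binomial GLM for the location coefficients puts
  # the outer search near the mode (the scale block starts at a mildly
  # overdispersed theta)
  beta_p0 <- tryCatch({
    cf <- stats::coef(stats::glm.fit(
      design$X_p, cbind(design$y, design$n_trials - design$y),
      family = stats::binomial()))
    ifelse(is.finite(cf), pmin(pmax(cf, -10), 10), 0)
  }, error = function(e) numeric(ncol(design$X_p)))
  beta_t0 <- numeric(ncol(design$X_theta))
  beta_t0[colnames(design$X_theta) == "intercept"] <- 2
  pars <- list(beta_p = beta_p0,
               beta_theta = beta_t0,
               log_sd = numeric(3), cpc_raw = numeric(3),
               z_re = matrix(0, np, 3))
  obj <- TMB::MakeADFun(dat, pars, random = "z_re", DLL = "melsbb",
                        silent = !verbose)
  if (!is.finite(obj$fn(obj$par)))
    stop("non-finite log density at the initial parameter values",
         call. = FALSE)
  # box bounds keep the outer search away from numerically hopeless
  # regions (SDs in [e^-6, e^3], correlations bounded away from +/-1)
  lo <- ifelse(names(obj$par) == "log_sd", -6,
               ifelse(names(obj$par) == "cpc_raw", -6, -30))
  hi <- ifelse(names(obj$par) == "log_sd", 3,
               ifelse(names(obj$par) == "cpc_raw", 6, 30))
  ctl <- list(iter.max = 2000L, eval.max = 4000L)
  opt <- stats::nlminb(obj$par, obj$fn, obj$gr, lower = lo, upper = hi,
                       control = ctl)
  grad_max <- function(o, p) {
    g <- tryCatch(o$gr(p), error = function(e) NA_real_)
    if (anyNA(g)) Inf else max(abs(g))
  }
  gmax <- if (opt$convergence == 0) 0 else grad_max(obj, opt$par)
  if (opt$convergence != 0 && gmax > 1e-1) {
    # "false convergence" with a large score usually means the inner
    # (Laplace) solve was poisoned along the way; retry from the current
    # point, then via a two-phase fit (variance block held at its start
    # while the regression coefficients settle, then everything free)
    opt <- stats::nlminb(opt$par, obj$fn, obj$gr, lower = lo, upper = hi,
                         control = ctl)
    gmax <- grad_max(obj, opt$par)
    if (opt$convergence != 0 && gmax > 1e-1) {
      obj1 <- TMB::MakeADFun(dat, pars, random = "z_re", DLL = "melsbb",
                             silent = !verbose,
                             map = list(log_sd = factor(rep(NA, 3)),
                                        cpc_raw = factor(rep(NA, 3))))
      o1 <- stats::nlminb(obj1$par, obj1$fn, obj1$gr,
                          control = list(iter.max = 500L,
                                         eval.max = 1000L))
      obj2 <- TMB::MakeADFun(dat, obj1$env$parList(o1$par), random = "z_re",
                             DLL = "melsbb", silent = !verbose)
      o2 <- stats::nlminb(obj2$par, obj2$fn, obj2$gr, lower = lo,
                          upper = hi, control = ctl)
      g2 <- grad_max(obj2, o2$par)
      if (o2$convergence == 0 || g2 < gmax) {
        obj <- obj2; opt <- o2; gmax <- g2
      }
    }
    if (opt$convergence != 0 && gmax > 1e-1) {
      msg <- paste0("optimizer did not converge: ", opt$message,
                    " (max |gradient| = ", format(gmax, digits = 3), ")")
      if (permissive) warning(msg, call. = FALSE)
      else stop(msg, call. = FALSE)
    }
  }
  rep <- TMB::sdreport(obj, getReportCovariance = FALSE)
  est <- opt$par
  se <- sqrt(diag(rep$cov.fixed))
  adr <- summary(rep, select = "report")

  nm_p <- colnames(design$X_p); nm_t <- colnames(design$X_theta)
  idx_p <- which(names(est) == "beta_p")
  idx_t <- which(names(est) == "beta_theta")
  idx_s <- which(names(est) == "log_sd")
  idx_c <- which(names(est) == "cpc_raw")

  sd_est <- stats::setNames(adr[rownames(adr) == "sdv", "Estimate"],
                            c("u0", "u1", "v0"))
  sd_se <- stats::setNames(adr[rownames(adr) == "sdv", "Std. Error"],
                           c("u0", "u1", "v0"))
  rho_nm <- c("r_u0_u1", "r_u0_v0", "r_u1_v0")
  rho_est <- stats::setNames(adr[rownames(adr) == "rho", "Estimate"], rho_nm)
  rho_se <- stats::setNames(adr[rownames(adr) == "rho", "Std. Error"], rho_nm)

  z_hat <- matrix(obj$env$parList(opt$par)$z_re, np, 3)
  L <- cpc_chol(tanh(est[idx_c]))
  effects <- z_hat %*% t(diag(sd_est) %*% L)
  colnames(effects) <- c("u0", "u1", "v0")

  structure(list(
    estimates = list(beta_p = stats::setNames(est[idx_p], nm_p),
                     beta_theta = stats::setNames(est[idx_t], nm_t),
                     sd = sd_est, corr = rho_est),
    se = list(beta_p = stats::setNames(se[idx_p], nm_p),
              beta_theta = stats::setNames(se[idx_t], nm_t),
              sd = sd_se, corr = rho_se),
    par_internal = est, cov_fixed = rep$cov.fixed,
    idx = list(beta_p = idx_p, beta_theta = idx_t, log_sd = idx_s,
               cpc_raw = idx_c),
    effects = effects, design = design, priors = priors,
    objective = opt$objective, convergence = opt$convergence,
    message = opt$message, method = "laplace"
  ), class = "mels_fit")
}

#' Wald 95% intervals for every reported parameter
#'
#' Fixed effects use the direct normal interval; SDs are transformed from
#' the log scale; correlations from the Fisher-z scale (then clamped to
#' the valid range).
#'
#' @param fit a [fit_map_laplace()] result.
#' @param level interval level.
#' @return Data frame with columns `block`, `term`, `estimate`, `lower`,
#'   `upper`.
#' @export
fit_ci <- function(fit, level = 0.95) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  rows <- list()
  for (blk in c("beta_p", "beta_theta")) {
    e <- fit$estimates[[blk]]; s <- fit$se[[blk]]
    rows[[blk]] <- data.frame(block = blk, term = names(e), estimate = e,
                              lower = e - q * s, upper = e + q * s)
  }
  ls <- fit$par_internal[fit$idx$log_sd]
  lse <- sqrt(diag(fit$cov_fixed))[fit$idx$log_sd]
  rows$sd <- data.frame(block = "sd", term = names(fit$estimates$sd),
                        estimate = exp(ls),
                        lower = exp(ls - q * lse), upper = exp(ls + q * lse))
  r <- fit$estimates$corr; rs <- fit$se$corr
  zf <- atanh(pmin(pmax(r, -0.999), 0.999))
  zse <- rs / pmax(1 - r^2, 1e-6)     # delta method to Fisher-z scale
  rows$corr <- data.frame(block = "corr", term = names(r), estimate = r,
                          lower = tanh(zf - q * zse),
                          upper = tanh(zf + q * zse))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian posterior draws from a Laplace fit
#'
#' Samples the fixed effects, SDs and correlations from the multivariate
#' normal approximation at the mode (transformed parameters drawn on
#' their unconstrained scale).  Person effects are held at their
#' conditional modes in every draw, so downstream observation-level
#' quantities ignore residual person-effect uncertainty; this is the
#' documented approximation of the fast path, adequate for effect tables
#' and model comparison on identifiable fits.
#'
#' @param fit a [fit_map_laplace()] result.
#' @param n_draws number of draws.
#' @param seed integer seed.
#' @return A `mels_draws` object: list with matrices `beta_p`,
#'   `beta_theta`, `sd`, `corr` (one row per draw, named columns), array
#'   `effects` (n_draws x n_persons x 3) and `method = "laplace"`.
#' @export
draws_from_laplace <- function(fit, n_draws = 400L, seed = 1L) {
  stopifnot(inherits(fit, "mels_fit"))
  set.seed(seed)
  mu <- fit$par_internal
  Sig <- fit$cov_fixed
  Lt <- chol(Sig + diag(1e-12, nrow(Sig)))
  D <- matrix(stats::rnorm(n_draws * length(mu)), n_draws) %*% Lt
  D <- sweep(D, 2, mu, "+")
  bp <- D[, fit$idx$beta_p, drop = FALSE]
  colnames(bp) <- names(fit$estimates$beta_p)
  bt <- D[, fit$idx$beta_theta, drop = FALSE]
  colnames(bt) <- names(fit$estimates$beta_theta)
  sds <- exp(D[, fit$idx$log_sd, drop = FALSE])
  colnames(sds) <- names(fit$estimates$sd)
  rr <- t(apply(D[, fit$idx$cpc_raw, drop = FALSE], 1,
                function(z) cpc_corrs(tanh(z))))
  colnames(rr) <- names(fit$estimates$corr)
  np <- nrow(fit$effects)
  eff <- array(rep(fit$effects, each = n_draws),
               dim = c(n_draws, np, 3))
  structure(list(beta_p = bp, beta_theta = bt, sd = sds, corr = rr,
                 effects = eff, method = "laplace"),
            class = "mels_draws")
}

#' @export
print.mels_fit <- function(x, ...) {
  cat("Location-scale beta-binomial fit (", x$method, ")\n", sep = "")
  cat("persons:", nrow(x$effects), " observations:",
      length(x$design$y), "\n")
  cat("negative log posterior at mode:", format(x$objective), "\n\n")
  print(fit_ci(x), digits = 3)
  invisible(x)
}
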