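# Full-Bayes estimation through JAGS (Gibbs/slice sampling).  The
# marginal beta-binomial log pmf enters through the standard
# Poisson-zeros device (a latent per-observation success probability
# would put unbounded beta densities in the graph whenever theta < 1,
# where the beta is U-shaped, and stall the slice sampler).  The
# correlated person effects use the same non-centred
# canonical-partial-correlation construction as the compiled objective,
# with the scaled-Beta CPC priors that make the correlation matrix
# marginally LKJ(eta).

jags_model_string <- "
model {
  for (j in 1:Nobs) {
    a[j] <- ilogit(max(min(inprod(Xp[j,], beta_p[]) +
      u[person[j],1] + u[person[j],2] * zage[j], 15), -15)) * theta[j]
    theta[j] <- exp(max(min(inprod(Xt[j,], beta_theta[]) + u[person[j],3],
                            16), -16))
    zeros[j] ~ dpois(-(lchoose_ny[j] +
      loggam(y[j] + a[j]) + loggam(ntr[j] - y[j] + theta[j] - a[j]) -
      loggam(ntr[j] + theta[j]) + loggam(theta[j]) -
      loggam(a[j]) - loggam(theta[j] - a[j])))
  }
  for (i in 1:Nper) {
    for (k in 1:3) { zre[i,k] ~ dnorm(0, 1) }
    u[i,1] <- sdv[1] * zre[i,1]
    u[i,2] <- sdv[2] * (l21 * zre[i,1] + l22 * zre[i,2])
    u[i,3] <- sdv[3] * (l31 * zre[i,1] + l32 * zre[i,2] + l33 * zre[i,3])
  }
  for (jj in 1:P) { beta_p[jj] ~ dnorm(0, 1 / (sc_p[jj] * sc_p[jj])) }
  for (jj in 1:Q) { beta_theta[jj] ~ dnorm(0, 1 / (sc_t[jj] * sc_t[jj])) }
  for (k in 1:3) {
    sdv[k] ~ dt(0, 1 / (sd_scale * sd_scale), sd_df) T(0,)
  }
  for (m in 1:3) {
    zb[m] ~ dbeta(cpc_a[m], cpc_a[m])
    zc[m] <- 2 * zb[m] - 1
  }
  l21 <- zc[1]
  l22 <- sqrt(1 - zc[1] * zc[1])
  l31 <- zc[2]
  l32 <- zc[3] * sqrt(1 - zc[2] * zc[2])
  l33 <- sqrt(max(1 - zc[2] * zc[2] - l32 * l32, 1e-12))
  rho[1] <- l21
  rho[2] <- l31
  rho[3] <- l21 * l31 + l22 * l32
}
"

#' Fit the model by MCMC
#'
#' Full-Bayes estimation of the location-scale beta-binomial via Gibbs and
#' slice sampling (JAGS), with the marginal beta-binomial likelihood and
#' the person effects in the non-centred parametrization.  Runs are
#' exactly reproducible given `seed`, chain count and iteration settings.
#'
#' Convergence is screened on every fixed effect, SD and correlation: if
#' any split-chain R-hat exceeds `rhat_max` the fit errors (set
#' `permissive = TRUE` to get the draws back with a warning instead, e.g.
#' for degenerate fixtures where part of the model is unidentified).
#'
#' @param panel panel data frame or [build_design()] object.
#' @param spec a [mels_spec()]; ignored for a prebuilt design.
#' @param priors a [mels_priors()].
#' @param chains,warmup,draws MCMC settings (defaults 4 chains x 1000
#'   post-warmup draws).
#' @param thin thinning interval.
#' @param seed integer seed (per-chain RNGs derived from it).
#' @param rhat_max convergence threshold (default 1.05).
#' @param permissive downgrade convergence failure to a warning.
#' @param quiet suppress JAGS progress output.
#' @return A `mels_draws` object with matrices `beta_p`, `beta_theta`,
#'   `sd`, `corr` (draws in rows), array `effects`
#'   (n_draws x n_persons x 3), diagnostics `rhat` and `ess` (named),
#'   `divergences` (always 0: Gibbs samplers have no divergent
#'   transitions), and `chains`.
#' @export
fit_mcmc <- function(panel, spec = mels_spec(), priors = mels_priors(),
                     chains = 4L, warmup = 1000L, draws = 1000L,
                     thin = 1L, seed = 1L, rhat_max = 1.05,
                     permissive = FALSE, quiet = TRUE) {
  if (!requireNamespace("rjags", quietly = TRUE))
    stop("fit_mcmc requires the rjags package", call. = FALSE)
  design <- if (inherits(panel, "mels_design")) panel
            else build_design(panel, spec)
  np <- length(design$person_ids)
  eta <- priors$lkj_eta
  dat <- list(
    Nobs = length(design$y), Nper = np,
    P = ncol(design$X_p), Q = ncol(design$X_theta),
    Xp = unname(design$X_p), Xt = unname(design$X_theta),
    zage = design$z_age, y = design$y,
    ntr = rep(design$n_trials, length.out = length(design$y)),
    lchoose_ny = lchoose(rep(design$n_trials,
                             length.out = length(design$y)), design$y),
    zeros = integer(length(design$y)),
    person = design$person_index,
    sc_p = prior_scales(colnames(design$X_p), priors),
    sc_t = prior_scales(colnames(design$X_theta), priors),
    sd_df = priors$sd_df, sd_scale = priors$sd_scale,
    cpc_a = c(eta + 0.5, eta + 0.5, eta)
  )
  inits <- lapply(seq_len(chains), function(ch) {
    set.seed(seed * 1000L + ch)
    list(beta_p = stats::rnorm(dat$P, 0, 0.1),
         beta_theta = c(stats::rnorm(1, 2, 0.1),
                        stats::rnorm(dat$Q - 1L, 0, 0.1)),
         sdv = rep(1, 3), zb = rep(0.5, 3),
         zre = matrix(0, np, 3),
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = seed * 1000L + ch)
  })
  pb <- if (quiet) "none" else "text"
  jm <- rjags::jags.model(textConnection(jags_model_string), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = max(100L, warmup %/% 2L), quiet = quiet)
  stats::update(jm, warmup, progress.bar = pb)
  samp <- rjags::jags.samples(
    jm, c("beta_p", "beta_theta", "sdv", "rho", "u"),
    n.iter = draws * thin, thin = thin, progress.bar = pb)

  # collapse (param, draw, chain) arrays into draw matrices
  flat <- function(a) {
    d <- dim(a)                      # c(npar, niter, nchain)
    t(matrix(aperm(a, c(2, 3, 1)), d[2] * d[3], d[1]))
  }
  bp <- t(flat(samp$beta_p)); colnames(bp) <- colnames(design$X_p)
  bt <- t(flat(samp$beta_theta)); colnames(bt) <- colnames(design$X_theta)
  sds <- t(flat(samp$sdv)); colnames(sds) <- c("u0", "u1", "v0")
  rr <- t(flat(samp$rho)); colnames(rr) <- c("r_u0_u1", "r_u0_v0", "r_u1_v0")
  S <- nrow(bp)
  u <- samp$u                        # dims (np, 3, niter, nchain)
  dim(u) <- c(np * 3L, dim(u)[3L], dim(u)[4L])
  eff <- array(NA_real_, c(S, np, 3))
  um <- t(flat(u))                   # S x (np*3), column-major: u[i,k]
  for (k in 1:3) eff[, , k] <- um[, ((k - 1L) * np + 1L):(k * np)]

  scal <- cbind(bp, bt, sds, rr)
  rhat <- apply(scal, 2, split_rhat, chains = chains)
  ess <- apply(scal, 2, ess_bulk, chains = chains)
  bad <- rhat[is.finite(rhat) & rhat > rhat_max]
  if (length(bad)) {
    msg <- paste0("R-hat above ", rhat_max, " for: ",
                  paste0(names(bad), " (", round(bad, 3), ")",
                         collapse = ", "))
    if (permissive) warning(msg, call. = FALSE) else stop(msg, call. = FALSE)
  }
  structure(list(beta_p = bp, beta_theta = bt, sd = sds, corr = rr,
                 effects = eff, rhat = rhat, ess = ess,
                 divergences = 0L, chains = chains, method = "mcmc"),
            class = "mels_draws")
}

# Split-chain potential scale reduction factor on a single scalar chain
# stacked chain-major (draws of chain 1, then chain 2, ...).
split_rhat <- function(x, chains) {
  n <- length(x) %/% chains
  half <- n %/% 2L
  if (half < 2L) return(NA_real_)
  segs <- lapply(seq_len(chains) - 1L, function(c0) {
    xc <- x[(c0 * n + 1L):(c0 * n + n)]
    list(xc[seq_len(half)], xc[(half + 1L):(2L * half)])
  })
  segs <- unlist(segs, recursive = FALSE)
  m <- length(segs)
  means <- vapply(segs, mean, 0); vars <- vapply(segs, stats::var, 0)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# Bulk effective sample size from chain-stacked draws (initial monotone
# positive-sequence estimator on the pooled autocorrelations).
ess_bulk <- function(x, chains) {
  n <- length(x) %/% chains
  if (n < 4L) return(NA_real_)
  xm <- matrix(x, n, chains)
  xm <- sweep(xm, 2, colMeans(xm))
  v <- mean(apply(xm, 2, stats::var))
  if (v <= 0) return(NA_real_)
  max_lag <- min(n - 1L, 200L)
  rho <- rowMeans(vapply(seq_len(chains), function(ch) {
    ac <- stats::acf(xm[, ch], lag.max = max_lag, plot = FALSE,
                     demean = FALSE)$acf[, 1, 1]
    ac
  }, numeric(max_lag + 1L)))
  s <- 0; lag <- 1L
  while (lag + 1L <= max_lag) {
    pair <- rho[lag + 1L] + rho[lag + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    lag <- lag + 2L
  }
  chains * n / (1 + 2 * s)
}
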