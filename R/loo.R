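# Pareto-smoothed importance sampling (PSIS) and leave-one-out model
# comparison.  The importance ratios for observation i are 1/p(y_i | draw),
# whose right tail is stabilized by replacing the largest ratios with the
# order statistics of a generalized Pareto distribution fitted to them.

# Generalized Pareto fit to exceedances x > 0 by the profile-posterior
# method of Zhang & Stephens (2009), with the mild shape regularization
# used in PSIS practice.  Returns shape k and scale sigma for the cdf
# F(x) = 1 - (1 + k x / sigma)^(-1/k).
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  # candidate values of b = -k/sigma; negative b is the heavy-tail side
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_of_b <- vapply(b, function(bi) mean(log1p(-bi * x)), 0)
  l_prof <- n * (log(-b / k_of_b) - k_of_b - 1)
  w <- exp(l_prof - max(l_prof)); w <- w / sum(w)
  b_hat <- sum(b * w)
  k_hat <- mean(log1p(-b_hat * x))             # shape xi
  sigma <- -k_hat / b_hat
  k_hat <- (n * k_hat + 10 * 0.5) / (n + 10)   # weak prior toward 0.5
  c(k = k_hat, sigma = sigma)
}

gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Smooth one vector of log importance ratios; returns normalized log
# weights (logsumexp = 0) and the Pareto-k diagnostic.
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  if (M >= 5L) {
    ord <- order(lw)
    tail_idx <- ord[(S - M + 1L):S]
    cut <- exp(lw[ord[S - M]])
    exceed <- exp(lw[tail_idx]) - cut
    if (max(exceed) > 0) {
      fit <- gpd_fit(exceed[exceed > 0] + 1e-300)
      qs <- gpd_quantile((seq_len(M) - 0.5) / M, fit["k"], fit["sigma"])
      lw[tail_idx[order(lw[tail_idx])]] <- log(qs + cut)
      lw <- pmin(lw, 0)              # never exceed the pre-smoothing max
      k_hat <- unname(fit["k"])
    } else k_hat <- -Inf
  } else k_hat <- NA_real_
  lse <- matrixStats_logsumexp(lw)
  list(log_weights = lw - lse, k = k_hat)
}

matrixStats_logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO expected log predictive density
#'
#' Computes the Pareto-smoothed importance-sampling estimate of the
#' leave-one-out expected log pointwise predictive density (elpd) from a
#' draws-by-observations log-likelihood matrix, with the per-observation
#' Pareto-k diagnostics (values above 0.7 flag observations whose
#' importance ratios are too heavy-tailed to trust).
#'
#' @param loglik numeric matrix, one row per posterior draw, one column
#'   per observation (see [pointwise_loglik()]).
#' @return Object of class `"mels_loo"`: list with `elpd`, `se`,
#'   `pointwise` (per-observation elpd), `pareto_k`, `n_bad_k`.
#' @export
psis_loo <- function(loglik) {
  if (!is.matrix(loglik) || nrow(loglik) < 2L)
    stop("`loglik` must be a matrix with at least 2 draws", call. = FALSE)
  if (any(!is.finite(loglik)))
    stop("`loglik` contains non-finite values", call. = FALSE)
  n <- ncol(loglik)
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    ll <- loglik[, i]
    sm <- psis_smooth(-ll)           # ratios 1/p(y_i | draw)
    pointwise[i] <- matrixStats_logsumexp(sm$log_weights + ll)
    pareto_k[i] <- sm$k
  }
  structure(list(elpd = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k,
                 n_bad_k = sum(is.finite(pareto_k) & pareto_k > 0.7)),
            class = "mels_loo")
}

#' LOO for a fitted model
#'
#' Convenience wrapper: draws from the fit (Gaussian approximation for
#' Laplace fits, the MCMC draws themselves otherwise), evaluates the
#' observation-level log-likelihood conditional on the person effects,
#' and runs [psis_loo()].
#'
#' @param fit a `mels_fit` or `mels_draws` object.
#' @param design the matching [build_design()]; taken from a `mels_fit`
#'   automatically.
#' @param n_draws draws for the Laplace path.
#' @param seed seed for the Laplace path.
#' @return A `mels_loo` object.
#' @export
loo_fit <- function(fit, design = NULL, n_draws = 400L, seed = 1L) {
  if (inherits(fit, "mels_fit")) {
    design <- design %||% fit$design
    draws <- draws_from_laplace(fit, n_draws = n_draws, seed = seed)
  } else if (inherits(fit, "mels_draws")) {
    if (is.null(design)) stop("`design` required for draws input",
                              call. = FALSE)
    draws <- fit
  } else stop("`fit` must be a mels_fit or mels_draws", call. = FALSE)
  psis_loo(pointwise_loglik(draws, design))
}

#' Compare candidate models by LOO
#'
#' Ranks models by elpd and applies a parsimony-respecting selection rule:
#' models are supplied in increasing order of complexity, and a more
#' complex candidate replaces the current choice only when its elpd
#' improvement over it exceeds the standard error of the pointwise elpd
#' difference.  With that rule a richer model that fits no better than a
#' simpler one is never selected.
#'
#' @param loos named list of `mels_loo` objects fitted to the same
#'   observations, ordered from simplest to most complex model.
#' @return Data frame (one row per model, input order) with columns
#'   `model`, `elpd`, `se`, `elpd_diff` and `se_diff` (both vs the
#'   highest-elpd model), `rank`, and `selected` (TRUE for exactly one
#'   row).
#' @export
compare_models <- function(loos) {
  stopifnot(length(loos) >= 1L, all(vapply(loos, inherits, TRUE, "mels_loo")))
  ns <- vapply(loos, function(l) length(l$pointwise), 0L)
  if (length(unique(ns)) != 1L)
    stop("models were fitted to different numbers of observations",
         call. = FALSE)
  if (is.null(names(loos)))
    names(loos) <- paste0("model", seq_along(loos))
  elpds <- vapply(loos, `[[`, 0, "elpd")
  best <- which.max(elpds)
  diff_se <- function(i, j) {
    if (i == j) return(0)
    d <- loos[[i]]$pointwise - loos[[j]]$pointwise
    sqrt(length(d) * stats::var(d))
  }
  chosen <- 1L
  for (m in seq_along(loos)[-1L]) {
    if (elpds[m] - elpds[chosen] > diff_se(m, chosen)) chosen <- m
  }
  out <- data.frame(
    model = names(loos),
    elpd = elpds,
    se = vapply(loos, `[[`, 0, "se"),
    elpd_diff = elpds - elpds[best],
    se_diff = vapply(seq_along(loos), diff_se, 0, j = best),
    rank = rank(-elpds, ties.method = "first"),
    selected = seq_along(loos) == chosen
  )
  rownames(out) <- NULL
  out
}

#' @export
print.mels_loo <- function(x, ...) {
  cat("PSIS-LOO: elpd ", format(x$elpd, digits = 6), " (se ",
      format(x$se, digits = 3), "), ", length(x$pointwise),
      " observations, ", x$n_bad_k, " with Pareto-k > 0.7\n", sep = "")
  invisible(x)
}
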