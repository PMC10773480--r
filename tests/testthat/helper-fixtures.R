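# Small fixtures built in code, shared across test files.

# Hand-written 3-row toy panel (two persons, one of them twice).
toy_panel <- function() {
  data.frame(
    person_id = c("a", "a", "b"),
    wave = c(1L, 2L, 1L),
    age_years = c(70, 72, 80),
    year_turned_65 = c(1997L, 1997L, 1987L),
    sex = c("female", "female", "male"),
    education = c("secondary", "secondary", "none"),
    adl_count = c(0L, 1L, 2L),
    test_issue = c(0L, 0L, 1L),
    score = c(12L, 10L, 6L),
    n_trials = 20L
  )
}

# Small simulated cohort reused by several files (cached per session).
small_cohort <- local({
  cache <- NULL
  function(n_persons = 150L, seed = 11L) {
    if (is.null(cache))
      cache <<- generate_cohort(
        cohort_config(n_persons = n_persons, dropout = dropout_mcar()),
        seed = seed)
    cache
  }
})

grid_params <- function() {
  expand.grid(p = c(0.1, 0.5, 0.9), theta = c(0.5, 2, 20, 200),
              n = c(1L, 20L))
}

# Brute-force recomputation of the joint density, written independently
# of the implementation: quadrature pmf per row, explicit trivariate
# normal algebra, explicit prior formulas.
oracle_joint <- function(design, fe, re, effects, priors) {
  ll <- 0
  for (j in seq_along(design$y)) {
    i <- design$person_index[j]
    eta_p <- sum(design$X_p[j, ] * fe$beta_p) +
      effects[i, 1] + effects[i, 2] * design$z_age[j]
    eta_t <- sum(design$X_theta[j, ] * fe$beta_theta) + effects[i, 3]
    pars <- bb_params(plogis(min(max(eta_p, -15), 15)),
                      exp(min(max(eta_t, -16), 16)),
                      rep(design$n_trials, length.out = length(design$y))[j])
    ll <- ll + log(bb_pmf_oracle(design$y[j], pars))
  }
  Sigma <- diag(re$sd) %*% re$corr %*% diag(re$sd)
  for (i in seq_len(nrow(effects))) {
    e <- effects[i, ]
    ll <- ll - 0.5 * (drop(e %*% solve(Sigma) %*% e) +
                        log(det(Sigma)) + 3 * log(2 * pi))
  }
  sc_p <- ifelse(names(fe$beta_p) == "intercept",
                 priors$intercept_scale, priors$slope_scale)
  sc_t <- ifelse(names(fe$beta_theta) == "intercept",
                 priors$intercept_scale, priors$slope_scale)
  ll + sum(dnorm(fe$beta_p, 0, sc_p, log = TRUE)) +
    sum(dnorm(fe$beta_theta, 0, sc_t, log = TRUE)) +
    sum(dt(re$sd / priors$sd_scale, priors$sd_df, log = TRUE) -
          log(priors$sd_scale) + log(2)) +
    (priors$lkj_eta - 1) * log(det(re$corr))
}

five_person_fixture <- function(seed = 21L) {
  cc <- generate_cohort(cohort_config(n_persons = 5,
                                      dropout = dropout_none()),
                        seed = seed)
  design <- build_design(cc$panel, cc$truth$spec)
  set.seed(seed + 1L)
  fe <- mels_fixef(
    setNames(rnorm(ncol(design$X_p), 0, 0.3), colnames(design$X_p)),
    setNames(c(2, rnorm(ncol(design$X_theta) - 1, 0, 0.3)),
             colnames(design$X_theta)))
  corr <- matrix(c(1, 0.3, -0.2, 0.3, 1, 0.1, -0.2, 0.1, 1), 3)
  re <- mels_ranef(0.6, 0.3, 0.9, corr)
  effects <- matrix(rnorm(15, 0, 0.5), 5, 3)
  list(design = design, fe = fe, re = re, effects = effects)
}

# Truth used by the model-selection harness: a pronounced interior bend
# in the age profile (nonlinearity far exceeding sampling noise at a few
# hundred persons) with a mild dispersion profile so every candidate fit
# is numerically routine.
selection_truth <- function() {
  tr <- mels_truth(knot_values = c(67, 71, 75, 81))
  tr$fixef$beta_p["age_rcs1"] <- -5
  tr$fixef$beta_p["age_rcs2"] <- 16
  tr$fixef$beta_theta <- c(
    intercept = 3.5, age_dec = -1, cohort_dec = -0.5, female = -0.3,
    edu_secondary = 0.3, edu_higher = 0.4, adl_between = -0.2,
    adl_within = -0.2, issue_between = -0.5, issue_within = -0.5)
  tr$ranef <- mels_ranef(0.55, 0.25, 0.8, tr$ranef$corr)
  tr
}
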