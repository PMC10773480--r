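# The joint probabilistic model: linear predictors, joint density versus
# a brute-force oracle, pointwise log-likelihood, forward simulation.

test_that("linear predictors reduce to the link identities", {
  fe <- mels_fixef(beta_p = c(a = 0, b = 0), beta_theta = c(a = 0))
  expect_equal(plogis(linear_predictor_p(c(1, 1), fe)), 0.5)
  expect_equal(exp(linear_predictor_theta(1, fe)), 1)
  # random intercept shifts the odds multiplicatively
  expect_equal(plogis(linear_predictor_p(c(1, 0), fe, u0 = log(3))), 0.75)
  # at the centring age the random slope vanishes
  expect_equal(linear_predictor_p(c(1, 0), fe, u0 = 0.2, u1 = 5, z_age = 0),
               0.2)
  # a -2.25 per-decade dispersion coefficient at one decade
  fe2 <- mels_fixef(beta_p = 0, beta_theta = c(int = 0, age = -2.25))
  expect_equal(linear_predictor_theta(c(0, 1), fe2), -2.25)
  expect_error(linear_predictor_p(c(1, 2, 3), fe), "dimension mismatch")
})

test_that("joint density matches the brute-force oracle on 5 persons", {
  fx <- five_person_fixture()
  pr <- mels_priors()
  got <- joint_log_density(fx$design, fx$fe, fx$re, fx$effects, pr)
  want <- oracle_joint(fx$design, fx$fe, fx$re, fx$effects, pr)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("joint density is additive in the data and reduces to the core", {
  # one person, one observation, all coefficients and effects zero:
  # the data term is the beta-binomial log pmf at p = 0.5, theta = 1
  p1 <- toy_panel()[3, ]
  d1 <- build_design(p1, mels_spec(knot_values = c(66, 71, 77, 85)))
  fe0 <- mels_fixef(setNames(numeric(ncol(d1$X_p)), colnames(d1$X_p)),
                    setNames(numeric(ncol(d1$X_theta)),
                             colnames(d1$X_theta)))
  re0 <- mels_ranef(1, 1, 1)
  eff0 <- matrix(0, 1, 3)
  with_prior <- joint_log_density(d1, fe0, re0, eff0, mels_priors())
  no_prior <- joint_log_density(d1, fe0, re0, eff0, priors = NULL)
  data_term <- no_prior - sum(-0.5 * (0 + log(1) + log(2 * pi)) * 3)
  expect_equal(data_term,
               bb_log_pmf(p1$score, bb_params(0.5, 1, 20L)))
  # prior sensitivity: scaling the prior changes only the prior term
  wide <- joint_log_density(d1, fe0, re0, eff0,
                            mels_priors(intercept_scale = 50,
                                        slope_scale = 25))
  expect_false(isTRUE(all.equal(wide, with_prior)))
  expect_equal(wide - with_prior,
               (sum(dnorm(0, 0, c(50, rep(25, ncol(d1$X_p) - 1)),
                          log = TRUE)) +
                  sum(dnorm(0, 0, c(50, rep(25, ncol(d1$X_theta) - 1)),
                            log = TRUE))) -
                 (sum(dnorm(0, 0, c(5, rep(2.5, ncol(d1$X_p) - 1)),
                            log = TRUE)) +
                    sum(dnorm(0, 0, c(5, rep(2.5, ncol(d1$X_theta) - 1)),
                              log = TRUE))))
})

test_that("column permutation leaves the density invariant", {
  fx <- five_person_fixture()
  pr <- mels_priors()
  base <- joint_log_density(fx$design, fx$fe, fx$re, fx$effects, pr)
  perm <- sample(seq_len(ncol(fx$design$X_p)))
  d2 <- fx$design
  d2$X_p <- d2$X_p[, perm]
  fe2 <- mels_fixef(fx$fe$beta_p[perm], fx$fe$beta_theta)
  # keep the intercept prior attached to the intercept column
  expect_equal(joint_log_density(d2, fe2, fx$re, fx$effects, priors = NULL),
               joint_log_density(fx$design, fx$fe, fx$re, fx$effects,
                                 priors = NULL))
})

test_that("pointwise log-likelihood rows sum to the data term", {
  fx <- five_person_fixture()
  draws <- list(beta_p = rbind(fx$fe$beta_p, fx$fe$beta_p),
                beta_theta = rbind(fx$fe$beta_theta, fx$fe$beta_theta),
                effects = array(rep(fx$effects, each = 2),
                                c(2, nrow(fx$effects), 3)))
  colnames(draws$beta_p) <- names(fx$fe$beta_p)
  colnames(draws$beta_theta) <- names(fx$fe$beta_theta)
  ll <- pointwise_loglik(draws, fx$design)
  expect_equal(dim(ll), c(2L, length(fx$design$y)))
  expect_equal(ll[1, ], ll[2, ])      # constant draws give identical rows
  data_term <- joint_log_density(fx$design, fx$fe, fx$re, fx$effects,
                                 priors = NULL) -
    sum(melsbb:::ranef_log_density(fx$effects, fx$re))
  expect_equal(sum(ll[1, ]), data_term, tolerance = 1e-10)
  expect_error(pointwise_loglik(list(beta_p = draws$beta_p), fx$design),
               "person effects")
})

test_that("forward simulation is reproducible and respects the truth", {
  cc <- generate_cohort(cohort_config(n_persons = 50,
                                      dropout = dropout_none()), seed = 5)
  design <- build_design(cc$panel, cc$truth$spec)
  tr <- cc$truth
  s1 <- simulate_from_model(design, tr$fixef, tr$ranef, seed = 9)
  s2 <- simulate_from_model(design, tr$fixef, tr$ranef, seed = 9)
  expect_identical(s1$scores, s2$scores)
  expect_identical(s1$effects, s2$effects)
  expect_true(all(s1$scores >= 0 & s1$scores <= 20))
  # zero random-effect SDs: everyone shares the population curves
  re0 <- mels_ranef(1e-10, 1e-10, 1e-10)
  s3 <- simulate_from_model(design, tr$fixef, re0, seed = 9)
  expect_lt(max(abs(s3$effects)), 1e-8)
})

test_that("raising dispersion lowers within-person score variance", {
  # same covariates, two dispersion regimes a decade apart in theta
  cc <- generate_cohort(cohort_config(n_persons = 400,
                                      dropout = dropout_none()), seed = 6)
  design <- build_design(cc$panel, cc$truth$spec)
  fe_lo <- cc$truth$fixef
  fe_hi <- mels_fixef(fe_lo$beta_p,
                      replace(fe_lo$beta_theta, 1,
                              fe_lo$beta_theta[1] + 3))
  re <- mels_ranef(1e-8, 1e-8, 1e-8)
  v <- function(fe, seed) {
    s <- simulate_from_model(design, fe, re, seed = seed)
    mean(tapply(s$scores, design$person_index, var), na.rm = TRUE)
  }
  expect_gt(v(fe_lo, 31), v(fe_hi, 31))
})
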