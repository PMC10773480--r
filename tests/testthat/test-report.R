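# Reporting surfaces: effect tables, the age curve, descriptive
# summaries, the baseline table.

constant_draws <- function(val_p, val_t, cols_p, cols_t, S = 50L) {
  structure(list(
    beta_p = matrix(rep(val_p, each = S), S,
                    dimnames = list(NULL, cols_p)),
    beta_theta = matrix(rep(val_t, each = S), S,
                        dimnames = list(NULL, cols_t)),
    sd = matrix(1, S, 3, dimnames = list(NULL, c("u0", "u1", "v0"))),
    corr = matrix(0, S, 3,
                  dimnames = list(NULL, c("r_u0_u1", "r_u0_v0", "r_u1_v0"))),
    effects = array(0, c(S, 2, 3)), method = "laplace"),
    class = "mels_draws")
}

test_that("or_table exponentiates draws and keeps interval ordering", {
  cols_p <- c("intercept", "age_dec", "age_rcs1", "cohort_dec", "female")
  d <- constant_draws(c(0.3, -0.2, 0.1, log(1.1), log(2)),
                      c(2, -1), cols_p, c("intercept", "age_dec"))
  tab <- or_table(d)
  # intercept and spline terms omitted; constant draws collapse the CrI
  expect_equal(tab$term, c("cohort_dec", "female"))
  expect_equal(tab$estimate[tab$term == "female"], 2)
  expect_equal(tab$lower[tab$term == "female"], 2)
  expect_equal(tab$upper[tab$term == "female"], 2)
  expect_true(all(tab$estimate > 0))
  # negative coefficient maps below 1
  d2 <- constant_draws(c(0, 0, 0, -0.5, -0.1), c(0, 0), cols_p,
                       c("intercept", "age_dec"))
  expect_lt(or_table(d2)$estimate[1], 1)
  expect_error(or_table(d, terms = "height"), "unknown term")
})

test_that("or summaries are transform-then-summarize", {
  set.seed(2)
  cols_p <- c("intercept", "female")
  S <- 4000
  dr <- constant_draws(c(0, 0), c(0), cols_p, "intercept", S = S)
  dr$beta_p[, "female"] <- rnorm(S, 0.2, 0.4)
  tab <- or_table(dr)
  # by Jensen the posterior mean OR exceeds exp(mean coefficient)
  expect_gt(tab$estimate, exp(mean(dr$beta_p[, "female"])))
  expect_equal(tab$estimate, mean(exp(dr$beta_p[, "female"])))
})

test_that("theta_table reports the log scale with optional ratios", {
  cols_t <- c("intercept", "age_dec", "female")
  d <- constant_draws(c(0, 0), c(4.5, -2.25, -0.43),
                      c("intercept", "age_dec"), cols_t)
  tab <- theta_table(d, variance_ratio = TRUE)
  expect_equal(tab$term, c("age_dec", "female"))
  expect_equal(tab$estimate[tab$term == "age_dec"], -2.25)
  expect_equal(tab$variance_ratio[tab$term == "age_dec"], exp(2.25))
  expect_equal(unique(tab$scale), "log-theta")
  # all-zero draws: every effect zero
  d0 <- constant_draws(c(0, 0), c(0, 0, 0), c("intercept", "age_dec"),
                       cols_t)
  expect_true(all(theta_table(d0)$estimate == 0))
})

test_that("age_curve recovers the generating age profile shape", {
  cc <- small_cohort()
  fit <- fit_map_laplace(cc$panel, cc$truth$spec)
  draws <- draws_from_laplace(fit, 300, seed = 4)
  curve <- suppressWarnings(age_curve(draws, fit$design, age_grid = 66:89))
  expect_equal(names(curve), c("age", "p", "lower", "upper"))
  expect_true(all(curve$lower <= curve$p & curve$p <= curve$upper))
  # declining profile, steeper over 80-89 than 66-75 (the generating
  # truth bends downward around 80)
  drop_young <- curve$p[curve$age == 66] - curve$p[curve$age == 75]
  drop_old <- curve$p[curve$age == 80] - curve$p[curve$age == 89]
  expect_gt(drop_young, 0)
  expect_gt(drop_old, drop_young)
  expect_warning(age_curve(draws, fit$design, age_grid = c(60, 95)),
                 "extrapolation")
  # zero coefficients: flat curve at one half
  d0 <- draws
  d0$beta_p[] <- 0
  flat <- age_curve(d0, fit$design, age_grid = 70:80)
  expect_equal(flat$p, rep(0.5, 11))
})

test_that("interval width shrinks as the cohort grows", {
  w <- vapply(c(150, 800), function(np) {
    cc <- generate_cohort(cohort_config(n_persons = np,
                                        dropout = dropout_mcar()),
                          seed = 61)
    fit <- fit_map_laplace(cc$panel, cc$truth$spec)
    curve <- age_curve(draws_from_laplace(fit, 300, seed = 5), fit$design,
                       age_grid = c(70, 75, 80))
    mean(curve$upper - curve$lower)
  }, 0)
  expect_lt(w[2], w[1])
})

test_that("mean_sd_summary excludes singletons and uses n-1", {
  p <- toy_panel()          # person a: scores 12, 10; person b: one obs
  s <- mean_sd_summary(p)
  expect_equal(nrow(s), 1)
  expect_equal(s$person_id, "a")
  expect_equal(s$mean_score, 11)
  expect_equal(s$sd_score, sd(c(12, 10)))
  # equal scores give SD zero
  p2 <- p; p2$score <- c(10L, 10L, 5L)
  expect_equal(mean_sd_summary(p2)$sd_score, 0)
})

test_that("baseline_table partitions completers and matches marginals", {
  cc <- generate_cohort(cohort_config(n_persons = 2500), seed = 33)
  tab <- baseline_table(cc$panel)
  n <- attr(tab, "n")
  expect_equal(n[["all"]], n[["non_completer"]] + n[["completer"]])
  fem <- tab[tab$characteristic == "sex" & tab$level == "female", ]
  se <- 3 * sqrt(0.545 * 0.455 / n[["all"]]) * 100
  expect_lt(abs(fem$all_pct_sd - 54.5), se)
  # single-person panel stays valid
  one <- cc$panel[cc$panel$person_id == cc$panel$person_id[1], ]
  t1 <- baseline_table(one)
  expect_equal(attr(t1, "n")[["all"]], 1L)
})
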