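# Covariate encodings: centring, knot placement, the restricted cubic
# spline basis, the within/between split, and the assembled design.

test_that("age and cohort centring produce decade-scale values", {
  expect_equal(center_age(74.2), 0)
  expect_equal(center_age(84.2), 1)
  expect_equal(center_age(65), -0.92)
  expect_equal(center_cohort(1999L), 0)
  expect_equal(center_cohort(2009L), 1)
  expect_equal(center_cohort(1989L), -1)
  expect_equal(center_age(80, center = 80), 0)   # configurable constant
})

test_that("knot placement follows the per-k quantile recommendations", {
  x <- seq(65, 90, length.out = 10001)            # ~uniform on [65, 90]
  expect_equal(select_knots(x, 4), 65 + 25 * c(0.05, 0.35, 0.65, 0.95),
               tolerance = 1e-3)
  expect_equal(select_knots(x, 3), 65 + 25 * c(0.10, 0.50, 0.90),
               tolerance = 1e-3)
  expect_equal(select_knots(x, 5),
               65 + 25 * c(0.05, 0.275, 0.50, 0.725, 0.95),
               tolerance = 1e-3)
  sym <- c(seq(0, 1, 0.01))
  expect_equal(select_knots(sym, 3)[2], stats::median(sym))
  expect_error(select_knots(rep(1, 100), 3), "degenerate")
  expect_error(select_knots(x, 6), "must be 3, 4 or 5")
})

test_that("rcs basis is linear outside the boundary knots", {
  knots <- c(-1, 0, 0.7, 2)
  # below the first knot every nonlinear column is exactly zero
  B_lo <- rcs_basis(seq(-3, -1.01, length.out = 50), knots)
  expect_true(all(B_lo[, -1] == 0))
  # beyond the last knot the second differences vanish
  xs <- seq(2.01, 5, length.out = 200)
  B_hi <- rcs_basis(xs, knots)
  d2 <- diff(B_hi, differences = 2)
  expect_lt(max(abs(d2)), 1e-8)
  # interior curvature exists (otherwise the basis would be degenerate)
  B_mid <- rcs_basis(seq(-1, 2, length.out = 200), knots)
  expect_gt(max(abs(diff(B_mid[, 2], differences = 2))), 0)
  expect_error(rcs_basis(0, c(1, 0, 2)), "increasing")
})

test_that("rcs basis matches an independent truncated-power evaluation", {
  # direct formula, written separately from the implementation
  knots <- c(0.2, 1.1, 3.0)
  x <- c(knots, 0.5, 2.2, 4)
  pp <- function(u) pmax(u, 0)^3
  t1 <- knots[1]; t2 <- knots[2]; t3 <- knots[3]
  ref <- (pp(x - t1) - pp(x - t2) * (t3 - t1) / (t3 - t2) +
            pp(x - t3) * (t2 - t1) / (t3 - t2)) / (t3 - t1)^2
  B <- rcs_basis(x, knots)
  expect_equal(unname(B[, 2]), ref)
  expect_equal(unname(B[, 1]), x)
})

test_that("within/between decomposition reconstructs exactly", {
  wb <- within_between(c(1, 1, 1), c(0, 1, 2))
  expect_equal(wb$between, c(1, 1, 1))
  expect_equal(wb$within, c(-1, 0, 1))
  # time-constant covariate: within identically zero
  wb2 <- within_between(c(1, 1, 2, 2), c(5, 5, 3, 3))
  expect_equal(wb2$within, rep(0, 4))
  # single-observation person
  wb3 <- within_between("z", 4)
  expect_equal(wb3$between, 4); expect_equal(wb3$within, 0)
  expect_error(within_between(integer(), numeric()), "non-empty")
  # property: reconstruction + zero person-means on random panels
  set.seed(31)
  for (rep in 1:5) {
    ids <- sample(1:40, 200, replace = TRUE)
    v <- rnorm(200)
    wb <- within_between(ids, v)
    expect_equal(wb$between + wb$within, v)
    expect_lt(max(abs(tapply(wb$within, ids, mean))), 1e-12)
  }
})

test_that("design assembly has the documented columns and is pure", {
  d <- build_design(toy_panel(), mels_spec(knots = 4,
                                           knot_values = c(66, 71, 77, 85)))
  expect_equal(colnames(d$X_p),
               c("intercept", "age_dec", "age_rcs1", "age_rcs2",
                 "cohort_dec", "female", "edu_secondary", "edu_higher",
                 "adl_between", "adl_within", "issue_between",
                 "issue_within"))
  expect_equal(ncol(d$X_p), 1 + 3 + 1 + 1 + 2 + 2 + 2)
  expect_equal(colnames(d$X_theta),
               c("intercept", "age_dec", "cohort_dec", "female",
                 "edu_secondary", "edu_higher", "adl_between",
                 "adl_within", "issue_between", "issue_within"))
  expect_false(anyNA(d$X_p)); expect_false(anyNA(d$X_theta))
  expect_equal(nrow(d$X_p), nrow(d$X_theta))
  expect_equal(length(d$z_age), nrow(d$X_p))
  # within columns average to zero inside each person
  for (col in c("adl_within", "issue_within"))
    expect_lt(max(abs(tapply(d$X_p[, col], d$person_index, mean))), 1e-12)
  # determinism: rebuilding gives bit-identical matrices
  d2 <- build_design(toy_panel(), mels_spec(knots = 4,
                                            knot_values = c(66, 71, 77, 85)))
  expect_identical(d$X_p, d2$X_p)
  expect_identical(d$X_theta, d2$X_theta)
})

test_that("interactions add exactly the documented product columns", {
  base <- build_design(toy_panel(), mels_spec(knot_values = c(66, 71, 77, 85)))
  withx <- build_design(toy_panel(),
                        mels_spec(knot_values = c(66, 71, 77, 85),
                                  interactions = c("sex", "adl")))
  added <- setdiff(colnames(withx$X_p), colnames(base$X_p))
  expect_equal(added, c("age_dec:female", "age_dec:adl_between",
                        "age_dec:adl_within"))
  expect_equal(withx$X_p[, "age_dec:female"],
               withx$X_p[, "age_dec"] * withx$X_p[, "female"])
  expect_error(mels_spec(interactions = "smoking"), "unknown interaction")
})

test_that("panel validation enforces the invariants", {
  p <- toy_panel()
  expect_silent(validate_panel(p))
  bad <- p; bad$age_years[1] <- 60
  expect_error(validate_panel(bad), "65")
  bad <- p; bad$score[1] <- 25L
  expect_error(validate_panel(bad), "n_trials")
  bad <- p; bad$wave[2] <- 1L
  expect_error(validate_panel(bad), "duplicate")
  bad <- p; bad$year_turned_65[2] <- 1990L
  expect_error(validate_panel(bad), "constant within person")
  bad <- p; bad$education[1] <- "phd"
  expect_error(validate_panel(bad), "education")
  bad <- p; bad$score[1] <- NA_integer_
  expect_message(out <- validate_panel(bad), "dropping 1")
  expect_equal(nrow(out), 2)
})

test_that("panels round-trip through CSV", {
  f <- tempfile(fileext = ".csv")
  write.csv(toy_panel(), f, row.names = FALSE)
  back <- read_panel_csv(f)
  expect_equal(back$score, toy_panel()$score)
  expect_s3_class(back$sex, "factor")
  unlink(f)
})
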