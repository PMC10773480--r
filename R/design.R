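#' Centre age in decades
#'
#' Age in years is centred on the sample-mean reference age (default 74.2)
#' and scaled to decades, so a unit change is ten years and zero is the
#' reference age at which random intercepts are interpreted.
#'
#' @param age_years numeric vector of ages (years).
#' @param center reference age in years (default 74.2).
#' @return `(age_years - center) / 10`.
#' @export
center_age <- function(age_years, center = 74.2) (age_years - center) / 10

#' Centre birth-cohort (year turned 65) in decades
#'
#' @param year_turned_65 integer calendar years.
#' @param center reference year (default 1999).
#' @return `(year - center) / 10`.
#' @export
center_cohort <- function(year_turned_65, center = 1999) {
  (year_turned_65 - center) / 10
}

#' Knot placement for restricted cubic splines
#'
#' Returns Harrell's recommended empirical-quantile knot positions:
#' k = 3: 0.10/0.50/0.90; k = 4: 0.05/0.35/0.65/0.95;
#' k = 5: 0.05/0.275/0.50/0.725/0.95.
#'
#' @param values numeric data the spline will be fitted to.
#' @param k number of knots, 3, 4 or 5.
#' @return Strictly increasing numeric vector of k knot locations.
#' @export
select_knots <- function(values, k = 4L) {
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  stop("`k` must be 3, 4 or 5", call. = FALSE))
  kn <- unname(stats::quantile(values, probs, type = 7, na.rm = FALSE))
  if (any(diff(kn) <= 0))
    stop("degenerate data: knots are not strictly increasing", call. = FALSE)
  kn
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline: piecewise cubic between the
#' knots, constrained to be linear beyond the boundary knots, with
#' continuous value and first two derivatives.  Column 1 is `x` itself;
#' columns `2..k-1` are the nonlinear terms
#' \deqn{(x - t_j)_+^3 - (x - t_{k-1})_+^3 \frac{t_k - t_j}{t_k - t_{k-1}}
#'       + (x - t_k)_+^3 \frac{t_{k-1} - t_j}{t_k - t_{k-1}}}
#' for `j = 1..k-2`, each divided by `(t_k - t_1)^2` so all columns share
#' the scale of `x`.
#'
#' @param x numeric vector.
#' @param knots strictly increasing numeric vector, length >= 3.
#' @return Matrix with `length(knots) - 1` columns named
#'   `"lin"`, `"nl1"`, `"nl2"`, ...
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3) stop("need at least 3 knots", call. = FALSE)
  if (any(diff(knots) <= 0))
    stop("`knots` must be strictly increasing", call. = FALSE)
  tk <- knots[k]; tk1 <- knots[k - 1L]
  scl <- (tk - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L,
                dimnames = list(NULL, c("lin", paste0("nl", seq_len(k - 2L)))))
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                        pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                        pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / scl
  }
  out
}

#' Within/between decomposition of a time-varying covariate
#'
#' Splits a covariate observed at each wave into its person-level mean
#' (carrying the between-individual effect) and the deviation from that
#' mean (the within-individual effect), so that `between + within`
#' reconstructs the covariate exactly and the within part averages to zero
#' inside every person.
#'
#' @param person_ids vector identifying the person for each row.
#' @param values numeric covariate aligned with `person_ids`.
#' @return List with numeric vectors `between` and `within`, same length
#'   as the input.
#' @export
within_between <- function(person_ids, values) {
  if (length(person_ids) != length(values) || length(values) == 0L)
    stop("`person_ids` and `values` must be non-empty and aligned",
         call. = FALSE)
  pm <- stats::ave(values, person_ids, FUN = mean)
  list(between = pm, within = values - pm)
}

#' Model specification for the location-scale beta-binomial
#'
#' Declares the design choices that turn a panel into design matrices:
#' the age-spline knot count for the location (p) predictor, optional
#' age-by-covariate interactions, centring constants, and reference
#' categories (male; no qualifications).  The links are fixed: logit for
#' the average probability `p`, log for the dispersion `theta`.  The
#' dispersion predictor always uses linear centred age in decades (the
#' single per-decade dispersion coefficient), and the person-level random
#' age slope also multiplies linear centred age.
#'
#' @param knots number of age-spline knots in the p-predictor: 3, 4 or 5,
#'   or 0 for a purely linear age term (the rival model in spline-vs-linear
#'   comparisons).
#' @param interactions character vector of covariates to interact with the
#'   linear age term in the p-predictor; any of `"sex"`, `"education"`,
#'   `"adl"`, `"test_issue"`.  Default none.
#' @param age_center,cohort_center centring constants (years).
#' @param knot_values optional explicit knot locations in years,
#'   overriding quantile-based placement.
#' @return Object of class `"mels_spec"`.
#' @export
mels_spec <- function(knots = 4L, interactions = character(),
                      age_center = 74.2, cohort_center = 1999,
                      knot_values = NULL) {
  if (!knots %in% c(0L, 3:5))
    stop("`knots` must be 3, 4 or 5 (or 0 for linear age)", call. = FALSE)
  bad <- setdiff(interactions, c("sex", "education", "adl", "test_issue"))
  if (length(bad))
    stop("unknown interaction term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(knots = as.integer(knots), interactions = interactions,
                 age_center = age_center, cohort_center = cohort_center,
                 knot_values = knot_values),
            class = "mels_spec")
}

#' Validate a long-format panel
#'
#' Checks the invariants of the person-wave table: required columns,
#' ages at least 65, scores within `[0, n_trials]`, unique
#' (person, wave) pairs, and a constant year-turned-65 within person.
#' Rows with missing values in modelled fields are dropped with a message.
#'
#' @param panel data frame with columns `person_id`, `wave`, `age_years`,
#'   `year_turned_65`, `sex` ("male"/"female"), `education`
#'   ("none"/"secondary"/"higher"), `adl_count` (0..5), `test_issue` (0/1),
#'   `score`, and optionally `n_trials` (default 20).
#' @return The validated (possibly row-filtered) panel, with `sex` and
#'   `education` as factors with fixed reference levels.
#' @export
validate_panel <- function(panel) {
  need <- c("person_id", "wave", "age_years", "year_turned_65", "sex",
            "education", "adl_count", "test_issue", "score")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(panel$n_trials)) panel$n_trials <- 20L
  cc <- stats::complete.cases(panel[need])
  if (any(!cc)) {
    message("dropping ", sum(!cc), " row(s) with missing modelled fields")
    panel <- panel[cc, , drop = FALSE]
  }
  if (nrow(panel) == 0L) stop("panel has no complete rows", call. = FALSE)
  if (any(panel$age_years < 65))
    stop("all ages must be >= 65", call. = FALSE)
  if (any(panel$score < 0 | panel$score > panel$n_trials))
    stop("scores must lie in [0, n_trials]", call. = FALSE)
  if (anyDuplicated(panel[c("person_id", "wave")]))
    stop("duplicate (person_id, wave) rows", call. = FALSE)
  if (any(tapply(panel$year_turned_65, panel$person_id,
                 function(v) length(unique(v))) != 1L))
    stop("`year_turned_65` must be constant within person", call. = FALSE)
  bad_sex <- setdiff(unique(as.character(panel$sex)), c("male", "female"))
  if (length(bad_sex))
    stop("unknown sex level(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  bad_edu <- setdiff(unique(as.character(panel$education)),
                     c("none", "secondary", "higher"))
  if (length(bad_edu))
    stop("unknown education level(s): ", paste(bad_edu, collapse = ", "),
         call. = FALSE)
  if (!all(panel$test_issue %in% c(0, 1)))
    stop("`test_issue` must be 0/1", call. = FALSE)
  panel$sex <- factor(as.character(panel$sex), levels = c("male", "female"))
  panel$education <- factor(as.character(panel$education),
                            levels = c("none", "secondary", "higher"))
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  rownames(panel) <- NULL
  panel
}

#' Build design matrices for both linear predictors
#'
#' Encodes the panel exactly as the model expects: the p-predictor gets an
#' intercept, the restricted-cubic-spline age basis (centred decades),
#' cohort in centred decades, female and education dummies (reference:
#' male, no qualifications), and the between/within split of the ADL count
#' and the interviewer test-issue indicator; the theta-predictor carries
#' the same covariates but with linear age only.  `z_age` is the centred
#' age in decades that multiplies the person-level random slope.
#'
#' @param panel a validated panel (see [validate_panel()]); validated here
#'   if not already.
#' @param spec a [mels_spec()].
#' @return Object of class `"mels_design"`: list with matrices `X_p`,
#'   `X_theta`, vector `z_age`, `person_index` (1-based person number per
#'   row), `person_ids` (unique ids in index order), `knots` (years),
#'   `y`, `n_trials`, and the `spec`.
#' @export
build_design <- function(panel, spec = mels_spec()) {
  panel <- validate_panel(panel)
  z_age <- center_age(panel$age_years, spec$age_center)
  z_coh <- center_cohort(panel$year_turned_65, spec$cohort_center)

  if (spec$knots == 0L) {
    knots_yrs <- range(panel$age_years)
    S <- cbind(age_dec = z_age)
  } else {
    knots_yrs <- spec$knot_values %||%
      select_knots(panel$age_years, spec$knots)
    S <- rcs_basis(z_age, center_age(knots_yrs, spec$age_center))
    colnames(S) <- c("age_dec", paste0("age_rcs", seq_len(ncol(S) - 1L)))
  }

  female <- as.numeric(panel$sex == "female")
  edu_sec <- as.numeric(panel$education == "secondary")
  edu_high <- as.numeric(panel$education == "higher")
  adl <- within_between(panel$person_id, panel$adl_count)
  iss <- within_between(panel$person_id, panel$test_issue)

  common <- cbind(cohort_dec = z_coh, female = female,
                  edu_secondary = edu_sec, edu_higher = edu_high,
                  adl_between = adl$between, adl_within = adl$within,
                  issue_between = iss$between, issue_within = iss$within)

  X_p <- cbind(intercept = 1, S, common)
  for (term in spec$interactions) {
    cols <- switch(term,
                   sex = cbind(`age_dec:female` = z_age * female),
                   education = cbind(`age_dec:edu_secondary` = z_age * edu_sec,
                                     `age_dec:edu_higher` = z_age * edu_high),
                   adl = cbind(`age_dec:adl_between` = z_age * adl$between,
                               `age_dec:adl_within` = z_age * adl$within),
                   test_issue = cbind(
                     `age_dec:issue_between` = z_age * iss$between,
                     `age_dec:issue_within` = z_age * iss$within))
    X_p <- cbind(X_p, cols)
  }
  X_theta <- cbind(intercept = 1, age_dec = z_age, common)

  ids <- unique(panel$person_id)
  structure(list(
    X_p = X_p, X_theta = X_theta, z_age = z_age,
    person_index = match(panel$person_id, ids), person_ids = ids,
    knots = knots_yrs, y = panel$score,
    n_trials = panel$n_trials, spec = spec, panel = panel
  ), class = "mels_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a long-format panel from CSV
#'
#' @param path CSV file with a header row holding the panel columns.
#' @return Validated panel data frame.
#' @export
read_panel_csv <- function(path) {
  validate_panel(utils::read.csv(path, stringsAsFactors = FALSE))
}
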