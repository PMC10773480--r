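#' Configuration of the synthetic ageing-cohort generator
#'
#' Defaults emulate the structure of a large English ageing panel: about
#' ten thousand core participants aged 65+, interviewed at up to 7 waves
#' two years apart, contributing on average 3.4 waves, with baseline
#' covariate marginals (sex 54.5% female; education 47.9/28.9/23.2%
#' none/secondary/higher; 78.2% with no ADL difficulty; 12.5% with an
#' interviewer-recorded test issue).
#'
#' @param n_persons number of persons.
#' @param max_waves maximum waves (default 7).
#' @param wave_spacing_years calendar years between waves (default 2).
#' @param baseline_year calendar year of wave 1 (default 2002).
#' @param age_mean,age_sd,age_min baseline age distribution: normal,
#'   truncated below at `age_min`.
#' @param p_female probability of female sex.
#' @param p_education probabilities for none/secondary/higher.
#' @param p_adl baseline probabilities of ADL-difficulty counts 0..5.
#' @param adl_up,adl_down per-wave probabilities that the ADL count moves
#'   up or down one step (clamped to 0..5); upward drift mimics ageing.
#' @param p_issue baseline probability of an interviewer-recorded test
#'   issue.
#' @param issue_on,issue_stay per-wave transition probabilities
#'   P(issue | no issue before) and P(issue | issue before); the defaults
#'   have stationary rate close to the baseline rate while generating
#'   within-person variation.
#' @param dropout dropout mechanism: `dropout_none()`, `dropout_mcar()` or
#'   `dropout_covariate()`.
#' @return Object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_persons = 9873L, max_waves = 7L,
                          wave_spacing_years = 2, baseline_year = 2002L,
                          age_mean = 70.5, age_sd = 6.4, age_min = 65,
                          p_female = 0.545,
                          p_education = c(none = 0.479, secondary = 0.289,
                                          higher = 0.232),
                          p_adl = c(0.782, 0.117, 0.053, 0.030, 0.015, 0.004),
                          adl_up = 0.15, adl_down = 0.05,
                          p_issue = 0.125, issue_on = 0.08, issue_stay = 0.45,
                          dropout = dropout_covariate()) {
  if (n_persons < 1) stop("`n_persons` must be >= 1", call. = FALSE)
  if (max_waves < 1) stop("`max_waves` must be >= 1", call. = FALSE)
  p_education <- p_education / sum(p_education)
  p_adl <- p_adl / sum(p_adl)
  stopifnot(p_female >= 0, p_female <= 1, p_issue >= 0, p_issue <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

#' Dropout mechanisms
#'
#' `dropout_none()` keeps every person for all waves.  `dropout_mcar(rate)`
#' removes each person after every completed wave with constant probability
#' `rate`, independent of everything (the default rate gives a mean of 3.4
#' observed waves out of 7).  `dropout_covariate()` makes the per-wave
#' leaving hazard logistic in baseline age, education, current ADL count
#' and current test-issue status, so that non-completers are older, less
#' educated and frailer, qualitatively matching observed completer
#' contrasts; the intercept is calibrated so the mean observed wave count
#' stays near 3.4.
#'
#' @param rate per-wave MCAR dropout probability.
#' @param intercept,age_per_decade,edu_secondary,edu_higher,adl,issue
#'   logistic-hazard coefficients; age enters as (baseline age - 70.5)/10.
#' @return A dropout-mechanism description (class `"dropout_mechanism"`).
#' @export
dropout_mcar <- function(rate = 0.2575) {
  stopifnot(rate >= 0, rate <= 1)
  structure(list(type = "mcar", rate = rate), class = "dropout_mechanism")
}

#' @rdname dropout_mcar
#' @export
dropout_none <- function() {
  structure(list(type = "none"), class = "dropout_mechanism")
}

#' @rdname dropout_mcar
#' @export
dropout_covariate <- function(intercept = -1.10, age_per_decade = 0.55,
                              edu_secondary = -0.30, edu_higher = -0.50,
                              adl = 0.20, issue = 0.45) {
  structure(list(type = "covariate", intercept = intercept,
                 age_per_decade = age_per_decade,
                 edu_secondary = edu_secondary, edu_higher = edu_higher,
                 adl = adl, issue = issue),
            class = "dropout_mechanism")
}

#' Default generating truth for synthetic cohorts
#'
#' Fixed effects set to published posterior-mean associations from a
#' large English ageing cohort's word-recall analysis: on the location
#' (logit p) side, odds ratios 1.24 (female), 1.30 (secondary education),
#' 1.52 (higher education), 1.17 (cohort per decade), 0.94/0.98 (ADL
#' between/within), 0.58/0.82 (test-issue between/within); on the
#' dispersion (log theta) side, -2.25 per decade of age, +0.45 (secondary
#' education), -0.43 (female), -0.26/-0.25 (ADL between/within),
#' -3.93/-2.51 (test-issue between/within), -1.51 (cohort per decade);
#' random-effect correlations 0.37 (u0,u1), 0.45 (u0,v0), 0.31 (u1,v0).
#' Quantities not publicly reported (intercepts, the age spline for p, the
#' higher-education dispersion effect, random-effect SDs) are generator
#' defaults chosen for realism: the age curve declines faster after about
#' age 80, the dispersion intercept makes scores near-binomial at 65 and
#' strongly overdispersed by the late 80s, and SDs give plausible
#' between-person spread in both submodels.
#'
#' @param knot_values age-spline knot locations in years.
#' @return List with elements `fixef` ([mels_fixef()]),
#'   `ranef` ([mels_ranef()]), `spec` ([mels_spec()]) and `n_trials`.
#' @export
mels_truth <- function(knot_values = c(66, 71, 77.5, 86)) {
  spec <- mels_spec(knots = length(knot_values), knot_values = knot_values)
  beta_p <- c(
    intercept = -0.10,
    age_dec = -0.22,
    age_rcs1 = -0.55,
    age_rcs2 = 1.00,
    cohort_dec = log(1.17),
    female = log(1.24),
    edu_secondary = log(1.30),
    edu_higher = log(1.52),
    adl_between = log(0.94),
    adl_within = log(0.98),
    issue_between = log(0.58),
    issue_within = log(0.82)
  )
  beta_theta <- c(
    intercept = 4.50,
    age_dec = -2.25,
    cohort_dec = -1.51,
    female = -0.43,
    edu_secondary = 0.45,
    edu_higher = 0.65,
    adl_between = -0.26,
    adl_within = -0.25,
    issue_between = -3.93,
    issue_within = -2.51
  )
  corr <- matrix(c(1, 0.37, 0.45,
                   0.37, 1, 0.31,
                   0.45, 0.31, 1), 3, 3, byrow = TRUE)
  list(fixef = mels_fixef(beta_p, beta_theta),
       ranef = mels_ranef(0.55, 0.25, 1.00, corr),
       spec = spec, n_trials = 20L)
}

# Truncated-normal sampler (lower truncation only) via inverse cdf.
rtnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (1 - p_lo), mean, sd)
}

#' Apply a monotone dropout mechanism to a panel
#'
#' Once a person leaves they never return: the mechanism decides, after
#' each completed wave, whether the person contributes the next one.
#'
#' @param panel long-format panel (need not carry scores yet).
#' @param mechanism a dropout mechanism (see [dropout_mcar()]).
#' @param seed integer seed; `NULL` continues the RNG stream.
#' @return The panel restricted to retained person-waves.
#' @export
apply_dropout <- function(panel, mechanism, seed = NULL) {
  if (!inherits(mechanism, "dropout_mechanism"))
    stop("unknown dropout mechanism", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (mechanism$type == "none") return(panel)
  panel <- panel[order(panel$person_id, panel$wave), , drop = FALSE]
  if (mechanism$type == "mcar") {
    haz <- rep(mechanism$rate, nrow(panel))
  } else {
    base_age <- stats::ave(panel$age_years, panel$person_id,
                           FUN = function(a) a[1L])
    haz <- stats::plogis(
      mechanism$intercept +
        mechanism$age_per_decade * (base_age - 70.5) / 10 +
        mechanism$edu_secondary * (panel$education == "secondary") +
        mechanism$edu_higher * (panel$education == "higher") +
        mechanism$adl * panel$adl_count +
        mechanism$issue * panel$test_issue)
  }
  leave_after <- stats::runif(nrow(panel)) < haz
  keep <- unlist(tapply(leave_after, panel$person_id, function(l) {
    w <- which(l)
    last <- if (length(w)) w[1L] else length(l)
    seq_along(l) <= last
  }), use.names = FALSE)
  out <- panel[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a synthetic ageing cohort with known truth
#'
#' Draws baseline covariates from the configured marginals, evolves the
#' time-varying covariates (ADL count, test-issue indicator) across waves
#' by simple Markov transitions, applies the dropout mechanism, and
#' simulates every word-recall score from the location-scale beta-binomial
#' model at the supplied truth.  The returned truth record carries
#' everything needed for parameter-recovery tests, including the sampled
#' person effects.
#'
#' @param config a [cohort_config()].
#' @param truth a truth list as returned by [mels_truth()] (the default).
#' @param seed integer seed controlling every random draw.
#' @return List with `panel` (a validated long-format data frame) and
#'   `truth` (the input truth plus `effects`, the n_persons x 3 matrix of
#'   latent person effects, and `seed`).
#' @export
generate_cohort <- function(config = cohort_config(), truth = mels_truth(),
                            seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  np <- as.integer(config$n_persons)

  age0 <- rtnorm_lower(np, config$age_mean, config$age_sd, config$age_min)
  sex <- ifelse(stats::runif(np) < config$p_female, "female", "male")
  education <- sample(c("none", "secondary", "higher"), np, TRUE,
                      prob = config$p_education)
  adl0 <- sample(0:5, np, TRUE, prob = config$p_adl)
  issue0 <- as.integer(stats::runif(np) < config$p_issue)
  year65 <- as.integer(round(config$baseline_year - (age0 - 65)))

  mw <- as.integer(config$max_waves)
  adl <- matrix(NA_integer_, np, mw); adl[, 1L] <- adl0
  iss <- matrix(NA_integer_, np, mw); iss[, 1L] <- issue0
  if (mw > 1L) for (w in 2:mw) {
    up <- stats::runif(np) < config$adl_up
    dn <- stats::runif(np) < config$adl_down
    adl[, w] <- pmin(pmax(adl[, w - 1L] + up - dn, 0L), 5L)
    p_on <- ifelse(iss[, w - 1L] == 1L, config$issue_stay, config$issue_on)
    iss[, w] <- as.integer(stats::runif(np) < p_on)
  }

  panel <- data.frame(
    person_id = rep(seq_len(np), each = mw),
    wave = rep(seq_len(mw), np),
    age_years = rep(age0, each = mw) +
      config$wave_spacing_years * (rep(seq_len(mw), np) - 1L),
    year_turned_65 = rep(year65, each = mw),
    sex = rep(sex, each = mw),
    education = rep(education, each = mw),
    adl_count = as.integer(t(adl)),
    test_issue = as.integer(t(iss)),
    score = 0L,
    n_trials = truth$n_trials
  )
  panel <- apply_dropout(panel, config$dropout)

  design <- build_design(panel, truth$spec)
  sim <- simulate_from_model(design, truth$fixef, truth$ranef)
  panel <- design$panel          # validated / ordered rows
  panel$score <- sim$scores

  truth$effects <- sim$effects
  truth$seed <- seed
  list(panel = panel, truth = truth)
}
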