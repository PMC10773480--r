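# Post-processing of fits into the standard reporting surfaces: effect
# tables on the odds-ratio and log-dispersion scales, the age prediction
# curve, per-person mean/SD descriptives, and a baseline summary table.
# Every posterior summary transforms each draw first and summarizes after
# (posterior of the odds ratio, never the exponential of a summarized
# coefficient).

as_mels_draws <- function(x, n_draws = 400L, seed = 1L) {
  if (inherits(x, "mels_draws")) return(x)
  if (inherits(x, "mels_fit"))
    return(draws_from_laplace(x, n_draws = n_draws, seed = seed))
  stop("expected a mels_draws or mels_fit object", call. = FALSE)
}

summarize_draws_cols <- function(mat, transform = identity, scale,
                                 level = 0.95) {
  a <- (1 - level) / 2
  tm <- transform(mat)
  data.frame(
    term = colnames(mat),
    estimate = colMeans(tm),
    lower = apply(tm, 2, stats::quantile, probs = a),
    upper = apply(tm, 2, stats::quantile, probs = 1 - a),
    scale = scale, row.names = NULL
  )
}

#' Odds-ratio table for the average-probability predictor
#'
#' Exponentiates every covariate coefficient draw of the p-predictor and
#' reports posterior means with equal-tailed 95% credible intervals.  The
#' intercept and the age-spline columns are omitted: a spline basis column
#' has no single-odds-ratio interpretation, so the age effect is reported
#' through [age_curve()] instead.
#'
#' @param draws a `mels_draws` or `mels_fit` object.
#' @param terms optional character vector restricting/ordering the rows;
#'   unknown terms are an error.
#' @param level credible level.
#' @return Data frame (an effect table) with columns `term`, `estimate`,
#'   `lower`, `upper`, `scale = "odds-ratio"`.
#' @export
or_table <- function(draws, terms = NULL, level = 0.95) {
  draws <- as_mels_draws(draws)
  cn <- colnames(draws$beta_p)
  keep <- setdiff(cn, c("intercept", grep("^age_", cn, value = TRUE)))
  if (!is.null(terms)) {
    bad <- setdiff(terms, cn)
    if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    keep <- terms
  }
  out <- summarize_draws_cols(draws$beta_p[, keep, drop = FALSE],
                              transform = exp, scale = "odds-ratio",
                              level = level)
  stopifnot(all(out$lower <= out$estimate + 1e-12),
            all(out$estimate <= out$upper + 1e-12), all(out$estimate > 0))
  out
}

#' Effect table for the log-dispersion predictor
#'
#' Posterior means and equal-tailed credible intervals of every covariate
#' coefficient in the predictor for log(theta); negative values mean
#' greater intraindividual variability.  `variance_ratio = TRUE` adds
#' `exp(-estimate)`, the multiplicative effect on the dispersion odds
#' (a rough variance-ratio reading of the log-scale coefficient).
#'
#' @param draws a `mels_draws` or `mels_fit` object.
#' @param terms optional restriction, as in [or_table()].
#' @param variance_ratio add an `exp(-coef)` summary column.
#' @param level credible level.
#' @return Effect-table data frame with `scale = "log-theta"`.
#' @export
theta_table <- function(draws, terms = NULL, variance_ratio = FALSE,
                        level = 0.95) {
  draws <- as_mels_draws(draws)
  cn <- colnames(draws$beta_theta)
  keep <- setdiff(cn, "intercept")
  if (!is.null(terms)) {
    bad <- setdiff(terms, cn)
    if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    keep <- terms
  }
  out <- summarize_draws_cols(draws$beta_theta[, keep, drop = FALSE],
                              scale = "log-theta", level = level)
  if (variance_ratio)
    out$variance_ratio <-
      colMeans(exp(-draws$beta_theta[, keep, drop = FALSE]))
  out
}

#' Predicted average probability across age
#'
#' For each grid age the age-spline basis is rebuilt at the fitted knots,
#' the p-predictor is evaluated per draw at a fixed covariate profile
#' (default: reference categories and zeros for the centred continuous
#' terms), inverse-logit transformed per draw, and then summarized.
#'
#' @param draws a `mels_draws` or `mels_fit` object.
#' @param design the [build_design()] the model was fitted to (provides
#'   knots and column order); taken from a `mels_fit` automatically.
#' @param age_grid ages in years at which to predict.
#' @param profile named numeric vector overriding covariate columns
#'   (e.g. `c(female = 1)`); unnamed covariates stay at 0.
#' @param level credible level.
#' @return Data frame with columns `age`, `p`, `lower`, `upper`.
#' @export
age_curve <- function(draws, design = NULL, age_grid = 65:90,
                      profile = NULL, level = 0.95) {
  if (inherits(draws, "mels_fit") && is.null(design)) design <- draws$design
  draws <- as_mels_draws(draws)
  if (is.null(design)) stop("`design` is required", call. = FALSE)
  if (min(age_grid) < min(design$knots) || max(age_grid) > max(design$knots))
    warning("age grid extends beyond the boundary knots; ",
            "predictions there are linear extrapolations", call. = FALSE)
  z <- center_age(age_grid, design$spec$age_center)
  if (design$spec$knots == 0L) {
    S <- cbind(age_dec = z)
  } else {
    S <- rcs_basis(z, center_age(design$knots, design$spec$age_center))
    colnames(S) <- c("age_dec", paste0("age_rcs", seq_len(ncol(S) - 1L)))
  }
  cn <- colnames(draws$beta_p)
  X <- matrix(0, length(age_grid), length(cn), dimnames = list(NULL, cn))
  X[, "intercept"] <- 1
  X[, colnames(S)] <- S
  for (nm in names(profile)) {
    if (!nm %in% cn) stop("unknown profile term: ", nm, call. = FALSE)
    X[, nm] <- profile[[nm]]
  }
  eta <- draws$beta_p %*% t(X)          # draws x ages
  p <- stats::plogis(eta)
  a <- (1 - level) / 2
  data.frame(age = age_grid, p = colMeans(p),
             lower = apply(p, 2, stats::quantile, probs = a),
             upper = apply(p, 2, stats::quantile, probs = 1 - a))
}

#' Per-person mean and SD of the score
#'
#' The descriptive surface behind mean-vs-variability scatterplots:
#' persons observed at least twice, their mean score and sample SD
#' (denominator n - 1).  With floor/ceiling-prone scores the SD is
#' typically lower at extreme means, an inverted-U over the mean.
#'
#' @param panel long-format panel.
#' @return Data frame with `person_id`, `n_obs`, `mean_score`, `sd_score`.
#' @export
mean_sd_summary <- function(panel) {
  panel <- validate_panel(panel)
  spl <- split(panel$score, panel$person_id)
  spl <- spl[lengths(spl) >= 2L]
  data.frame(person_id = names(spl),
             n_obs = lengths(spl),
             mean_score = vapply(spl, mean, 0),
             sd_score = vapply(spl, stats::sd, 0),
             row.names = NULL)
}

#' Baseline characteristics table, by completer status
#'
#' Baseline is each person's first included wave.  A completer contributes
#' every wave from their first included wave through the study's final
#' wave.  Categorical rows report counts and percentages; continuous rows
#' (age, score) report mean and SD.
#'
#' @param panel long-format panel.
#' @param final_wave last wave of the study (default: max wave present).
#' @return Data frame with columns `characteristic`, `level`, and for
#'   each of the three groups (all, non-completer, completer) a count/mean
#'   and a percent/SD column.
#' @export
baseline_table <- function(panel, final_wave = NULL) {
  panel <- validate_panel(panel)
  final_wave <- final_wave %||% max(panel$wave)
  per <- split(panel, panel$person_id)
  base <- do.call(rbind, lapply(per, function(d) d[which.min(d$wave), ]))
  complete <- vapply(per, function(d) {
    all(seq(min(d$wave), final_wave) %in% d$wave)
  }, TRUE)
  groups <- list(all = rep(TRUE, nrow(base)),
                 non_completer = !complete, completer = complete)
  num_row <- function(chr, v) {
    cells <- lapply(groups, function(g)
      c(mean(v[g]), if (sum(g) > 1L) stats::sd(v[g]) else NA_real_))
    data.frame(characteristic = chr, level = "mean (SD)",
               all = cells$all[1], all_pct_sd = cells$all[2],
               non_completer = cells$non_completer[1],
               non_completer_pct_sd = cells$non_completer[2],
               completer = cells$completer[1],
               completer_pct_sd = cells$completer[2])
  }
  cat_rows <- function(chr, f) {
    f <- factor(f)
    do.call(rbind, lapply(levels(f), function(lv) {
      cells <- lapply(groups, function(g) {
        n <- sum(f[g] == lv)
        c(n, if (sum(g)) 100 * n / sum(g) else NA_real_)
      })
      data.frame(characteristic = chr, level = lv,
                 all = cells$all[1], all_pct_sd = cells$all[2],
                 non_completer = cells$non_completer[1],
                 non_completer_pct_sd = cells$non_completer[2],
                 completer = cells$completer[1],
                 completer_pct_sd = cells$completer[2])
    }))
  }
  out <- rbind(
    num_row("age", base$age_years),
    cat_rows("sex", base$sex),
    cat_rows("education", base$education),
    cat_rows("adl_count", base$adl_count),
    cat_rows("test_issue", base$test_issue),
    num_row("score", base$score)
  )
  attr(out, "n") <- vapply(groups, sum, 0L)
  out
}
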