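# Threshold-versus-age regression: candidate model families, R^2-based
# selection, curve inversion for crossing ages, onset age and hearing
# progression time (HPT).
#
# Candidate families (y = threshold in dB HL, x = age in years):
#   power        y = a * x^b            (a > 0), 2 parameters
#   linear       y = c0 + c1*x                  2
#   logarithmic  y = c0 + c1*ln(x)              2
#   quadratic    y = c0 + c1*x + c2*x^2         3
# R^2 is always 1 - SS_res/SS_tot on the original threshold scale, so the
# nonlinear power fit is comparable with the lm-based families.

#' Candidate model families
#'
#' @return Character vector of family names in the canonical tie-break order
#'   used by [select_best()].
#' @export
model_families <- function() c("power", "logarithmic", "linear", "quadratic")

family_parameter_count <- function(family) {
  switch(family, power = 2L, linear = 2L, logarithmic = 2L, quadratic = 3L,
         ap_stop(sprintf("unknown model family '%s'", family),
                 "ap_validation_error"))
}

fitted_model <- function(family, params, r_squared, n, age_range) {
  structure(
    list(family = family, params = params, r_squared = r_squared,
         n = as.integer(n), age_range = as.numeric(age_range)),
    class = "progression_fit"
  )
}

#' @export
print.progression_fit <- function(x, ...) {
  cat(sprintf("<progression_fit> %s: %s | R^2 = %s | n = %d | ages %.2f-%.2f\n",
              x$family,
              paste(sprintf("%s=%.6g", names(x$params), x$params),
                    collapse = ", "),
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$n, x$age_range[1], x$age_range[2]))
  invisible(x)
}

#' Predict thresholds from a fitted progression model
#'
#' @param object A `progression_fit`.
#' @param ages Ages in years (positive).
#' @param ... Unused.
#' @return Predicted thresholds in dB HL.
#' @export
predict.progression_fit <- function(object, ages, ...) {
  p <- object$params
  switch(object$family,
    power       = p[["a"]] * ages^p[["b"]],
    linear      = p[["c0"]] + p[["c1"]] * ages,
    logarithmic = p[["c0"]] + p[["c1"]] * log(ages),
    quadratic   = p[["c0"]] + p[["c1"]] * ages + p[["c2"]] * ages^2
  )
}

definitional_r_squared <- function(observed, predicted) {
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  1 - ss_res / ss_tot
}

#' Fit a threshold-versus-age model
#'
#' Least-squares fit of one candidate family. The linear, logarithmic and
#' quadratic families are ordinary linear models; the power family is fitted
#' by Levenberg-Marquardt nonlinear least squares on the original threshold
#' scale, initialized from OLS on the log-log transform (observations with
#' threshold <= 0 excluded from the initialization only). R^2 is computed
#' definitionally on the threshold scale for every family.
#'
#' @param ages Ages in years (all > 0).
#' @param thresholds Thresholds in dB HL, same length as `ages`.
#' @param family One of [model_families()].
#' @return A `progression_fit` with fields `family`, `params`, `r_squared`,
#'   `n`, `age_range`.
#' @examples
#' x <- 10:70
#' fit_model(x, 2 * x^0.8, "power")
#' @export
fit_model <- function(ages, thresholds, family = model_families()) {
  family <- match.arg(family)
  ages <- as.numeric(ages)
  thresholds <- as.numeric(thresholds)
  if (length(ages) != length(thresholds)) {
    ap_stop("ages and thresholds must have equal length", "ap_validation_error")
  }
  ok <- !(is.na(ages) | is.na(thresholds))
  ages <- ages[ok]; thresholds <- thresholds[ok]
  n <- length(ages)
  p <- family_parameter_count(family)
  if (n < p + 1L) {
    ap_stop(sprintf("%s fit needs at least %d observations, got %d",
                    family, p + 1L, n),
            "ap_insufficient_data_error")
  }
  if (any(ages <= 0)) {
    ap_stop("all ages must be strictly positive", "ap_validation_error")
  }
  if (stats::sd(thresholds) == 0) {
    ap_stop("thresholds have zero variance; nothing to fit",
            "ap_degenerate_data_error")
  }

  params <- switch(family,
    linear = {
      co <- stats::coef(stats::lm(thresholds ~ ages))
      c(c0 = unname(co[1]), c1 = unname(co[2]))
    },
    logarithmic = {
      lx <- log(ages)
      co <- stats::coef(stats::lm(thresholds ~ lx))
      c(c0 = unname(co[1]), c1 = unname(co[2]))
    },
    quadratic = {
      co <- stats::coef(stats::lm(thresholds ~ ages + I(ages^2)))
      c(c0 = unname(co[1]), c1 = unname(co[2]), c2 = unname(co[3]))
    },
    power = fit_power(ages, thresholds)
  )

  fitted_model(
    family, params,
    r_squared = definitional_r_squared(
      thresholds,
      predict.progression_fit(fitted_model(family, params, NA, n,
                                           range(ages)), ages)),
    n = n, age_range = range(ages)
  )
}

fit_power <- function(ages, thresholds) {
  pos <- thresholds > 0
  if (sum(pos) >= 2L && length(unique(ages[pos])) >= 2L) {
    init_co <- stats::coef(stats::lm(log(thresholds[pos]) ~ log(ages[pos])))
    start <- list(a = exp(unname(init_co[1])), b = unname(init_co[2]))
  } else {
    start <- list(a = max(mean(thresholds), 1), b = 0.1)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      thresholds ~ a * ages^b,
      start = start,
      control = minpack.lm::nls.lm.control(
        maxiter = 1000, ftol = 1e-12, ptol = 1e-12, maxfev = 10000)),
    error = function(e) {
      ap_stop(sprintf(
        "power fit failed to converge (start a=%.4g, b=%.4g): %s",
        start$a, start$b, conditionMessage(e)),
        "ap_fit_failure_error")
    })
  co <- stats::coef(fit)
  c(a = unname(co[["a"]]), b = unname(co[["b"]]))
}

#' Select the best fit among candidate families
#'
#' Ranks fits on the same data by goodness of fit with a parsimony penalty:
#' the Schwarz (BIC-type) score n*log(1 - R^2) + p*log(n), lower is better,
#' which for a common dataset orders exactly like the residual sum of
#' squares penalized for parameter count. For families with equal parameter
#' counts this ordering coincides with ranking by R^2; a 3-parameter family
#' must improve R^2 materially, not marginally, to displace a 2-parameter
#' one, so the generating family of a power-law cohort is recovered rather
#' than over-fitted by the quadratic. Ties (including multiple exact fits
#' with R^2 = 1) are broken by fewer parameters, then by the fixed family
#' order power, logarithmic, linear, quadratic.
#'
#' @param fits Non-empty list of `progression_fit`s fitted on the same data.
#' @return The selected `progression_fit`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0L) {
    ap_stop("no candidate fits supplied", "ap_empty_input_error")
  }
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  n <- vapply(fits, `[[`, integer(1), "n")
  npar <- vapply(fits, function(f) family_parameter_count(f$family),
                 integer(1))
  fam_rank <- match(vapply(fits, `[[`, character(1), "family"),
                    model_families())
  score <- ifelse(1 - r2 <= 0, -Inf, n * log(pmax(1 - r2, 0))) +
    npar * log(n)
  fits[[order(score, npar, fam_rank)[1L]]]
}

#' Age at which a fitted curve attains a threshold level
#'
#' Inverts the fitted curve: the smallest age x in (0, 120\] years at which
#' the predicted threshold equals `level` on an upward (increasing) crossing.
#' The power family uses the closed form x = (level/a)^(1/b); the quadratic
#' family takes the smallest positive upward root. Ages outside the fitted
#' age range are returned with `extrapolated = TRUE` rather than refused.
#'
#' @param model A `progression_fit`.
#' @param level Threshold level in dB HL, in (-10, 120).
#' @return List with `age` (years) and `extrapolated` (logical).
#' @export
crossing_age <- function(model, level) {
  stopifnot(inherits(model, "progression_fit"))
  if (length(level) != 1L || is.na(level) || level <= -10 || level >= 120) {
    ap_stop("level must lie in (-10, 120) dB HL", "ap_domain_error")
  }
  max_age <- 120
  p <- model$params
  no_cross <- function() {
    ap_stop(sprintf(
      "%s model never attains %g dB on an upward crossing within (0, %g] years",
      model$family, level, max_age),
      "ap_no_crossing_error")
  }
  age <- switch(model$family,
    power = {
      if (p[["a"]] <= 0 || p[["b"]] <= 0 || level <= 0) no_cross()
      (level / p[["a"]])^(1 / p[["b"]])
    },
    linear = {
      if (p[["c1"]] <= 0) no_cross()
      (level - p[["c0"]]) / p[["c1"]]
    },
    logarithmic = {
      if (p[["c1"]] <= 0) no_cross()
      exp((level - p[["c0"]]) / p[["c1"]])
    },
    quadratic = {
      if (abs(p[["c2"]]) < .Machine$double.eps) {
        if (p[["c1"]] <= 0) no_cross()
        (level - p[["c0"]]) / p[["c1"]]
      } else {
        disc <- p[["c1"]]^2 - 4 * p[["c2"]] * (p[["c0"]] - level)
        if (disc < 0) no_cross()
        roots <- (-p[["c1"]] + c(-1, 1) * sqrt(disc)) / (2 * p[["c2"]])
        slope <- p[["c1"]] + 2 * p[["c2"]] * roots
        up <- roots[roots > 0 & roots <= max_age & slope > 0]
        if (length(up) == 0L) no_cross()
        min(up)
      }
    })
  if (!is.finite(age) || age <= 0 || age > max_age) no_cross()
  list(age = unname(age),
       extrapolated = age < model$age_range[1] || age > model$age_range[2])
}

#' Onset age of hearing loss
#'
#' The age at which the fitted PTA-versus-age curve crosses `level`
#' (default 25 dB HL), obtained by curve inversion.
#'
#' @param model A `progression_fit` on PTA-versus-age data.
#' @param level Onset threshold level (dB HL), default 25.
#' @return Onset age in years.
#' @export
onset_age <- function(model, level = 25) {
  crossing_age(model, level)$age
}

#' Hearing progression time (HPT)
#'
#' Years required for the fitted threshold to rise from `from` (default
#' 25 dB HL) to `to` (default 60 dB HL): the difference of the two crossing
#' ages. Positive for increasing curves.
#'
#' @param model A `progression_fit`.
#' @param from,to Threshold levels in dB HL, `from < to`.
#' @return HPT in years.
#' @export
hearing_progression_time <- function(model, from = 25, to = 60) {
  if (!(from < to)) {
    ap_stop("'from' level must be below 'to' level", "ap_validation_error")
  }
  crossing_age(model, to)$age - crossing_age(model, from)$age
}

#' Power model through two (age, threshold) points
#'
#' Constructs the unique power law y = a * x^b passing through `p1` and `p2`
#' (b = ln(y2/y1)/ln(x2/x1), a = y1/x1^b). R^2 is not applicable (`NA`).
#' Symmetric in its arguments.
#'
#' @param p1,p2 Numeric pairs `c(age_years, threshold_db)`; ages and
#'   thresholds strictly positive, ages distinct, thresholds distinct.
#' @return A `progression_fit` with family `"power"`.
#' @examples
#' m <- two_point_power_model(c(26.07, 25), c(65.30, 60))
#' hearing_progression_time(m)  # 39.23
#' @export
two_point_power_model <- function(p1, p2) {
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  x <- c(p1[1], p2[1]); y <- c(p1[2], p2[2])
  if (any(x <= 0) || any(y <= 0)) {
    ap_stop("both ages and both thresholds must be strictly positive",
            "ap_domain_error")
  }
  if (x[1] == x[2]) {
    ap_stop("the two points must have distinct ages", "ap_degenerate_data_error")
  }
  if (y[1] == y[2]) {
    ap_stop("the two points must have distinct thresholds",
            "ap_degenerate_data_error")
  }
  b <- log(y[2] / y[1]) / log(x[2] / x[1])
  a <- y[1] / x[1]^b
  fitted_model("power", c(a = a, b = b), r_squared = NA_real_,
               n = 2L, age_range = range(x))
}

#' Full progression summary of a cohort
#'
#' The cohort-level progression analysis: fits all requested families to
#' PTA-versus-age, selects the best by R^2 and inverts it for the onset age;
#' then fits a power model to each band's mean threshold versus age and
#' inverts for the `onset_level`/`progression_level` crossing ages and HPT.
#' A band whose fit or inversion fails is reported in place (with the error
#' message) while the remaining bands are still computed.
#'
#' @param records List of `audiogram_record`s (>= 4 with computable PTA).
#' @param bands List of `frequency_band`s; default [frequency_bands()].
#' @param families Families for the PTA model comparison; default all.
#' @param onset_level,progression_level Crossing levels in dB HL (25 and 60).
#' @return A `progression_summary`: `onset_age`, `onset_model`,
#'   `model_comparison` (per-family params and R^2), and `bands`, a list per
#'   band of `age_25`/`age_60` crossing ages, `hpt`, `extrapolated` flag and
#'   the band's power fit (or an `error` message).
#' @export
progression_summary <- function(records,
                                bands = frequency_bands(),
                                families = model_families(),
                                onset_level = 25,
                                progression_level = 60) {
  pta_df <- do.call(rbind, lapply(records, function(r) {
    pta <- tryCatch(compute_pta(r), ap_incomplete_audiogram_error =
                      function(e) NA_real_)
    data.frame(age = r$age, pta = pta)
  }))
  pta_df <- pta_df[!is.na(pta_df$pta), , drop = FALSE]
  if (is.null(pta_df) || nrow(pta_df) < 4L) {
    ap_stop("progression summary needs >= 4 subjects with a computable PTA",
            "ap_insufficient_data_error")
  }

  fits <- lapply(families, function(fam)
    tryCatch(fit_model(pta_df$age, pta_df$pta, fam),
             ap_error = function(e) NULL))
  names(fits) <- families
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L) {
    ap_stop("no candidate family could be fitted to PTA-versus-age",
            "ap_fit_failure_error")
  }
  best <- select_best(fits)
  onset <- tryCatch(onset_age(best, onset_level),
                    ap_no_crossing_error = function(e) NA_real_)

  band_res <- lapply(bands, function(bd) {
    tryCatch({
      bm <- vapply(records, function(r)
        tryCatch(suppressWarnings(band_mean(r, bd)),
                 ap_incomplete_audiogram_error = function(e) NA_real_),
        numeric(1))
      ages <- vapply(records, `[[`, numeric(1), "age")
      ok <- !is.na(bm)
      fit <- fit_model(ages[ok], bm[ok], "power")
      lo <- crossing_age(fit, onset_level)
      hi <- crossing_age(fit, progression_level)
      list(name = bd$name,
           age_25 = lo$age, age_60 = hi$age,
           hpt = hi$age - lo$age,
           extrapolated = lo$extrapolated || hi$extrapolated,
           model = fit, error = NULL)
    }, ap_error = function(e) {
      ap_warn(sprintf("band '%s' skipped: %s", bd$name, conditionMessage(e)),
              "ap_band_skipped_warning")
      list(name = bd$name, age_25 = NA_real_, age_60 = NA_real_,
           hpt = NA_real_, extrapolated = NA, model = NULL,
           error = conditionMessage(e))
    })
  })
  names(band_res) <- vapply(bands, `[[`, character(1), "name")

  structure(
    list(onset_age = onset,
         onset_level = onset_level,
         progression_level = progression_level,
         onset_model = best,
         model_comparison = lapply(fits, function(f)
           list(params = as.list(f$params), r_squared = f$r_squared)),
         selected_family = best$family,
         n_subjects = nrow(pta_df),
         bands = band_res),
    class = "progression_summary"
  )
}

#' @export
print.progression_summary <- function(x, ...) {
  cat(sprintf(
    "<progression_summary> n = %d | %s model | onset (%g dB): %s y\n",
    x$n_subjects, x$selected_family, x$onset_level,
    if (is.na(x$onset_age)) "not attained" else sprintf("%.2f", x$onset_age)))
  for (b in x$bands) {
    if (is.null(b$error)) {
      cat(sprintf("  %-5s %g dB at %.2f y, %g dB at %.2f y, HPT %.2f y%s\n",
                  b$name, x$onset_level, b$age_25, x$progression_level,
                  b$age_60, b$hpt,
                  if (isTRUE(b$extrapolated)) " (extrapolated)" else ""))
    } else {
      cat(sprintf("  %-5s unavailable: %s\n", b$name, b$error))
    }
  }
  invisible(x)
}

#' Serialize a progression summary
#'
#' @param x A `progression_summary`.
#' @param path Optional file path; when given, JSON is written there.
#' @return JSON string (invisibly if written to `path`).
#' @export
progression_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "progression_summary"))
  obj <- list(
    onset_age_years = x$onset_age,
    selected_family = x$selected_family,
    model_comparison = x$model_comparison,
    bands = lapply(unname(x$bands), function(b) {
      out <- list(name = b$name, age_25db = b$age_25, age_60db = b$age_60,
                  hpt_years = b$hpt, extrapolated = b$extrapolated)
      if (!is.null(b$model)) {
        out$model <- list(family = b$model$family,
                          params = as.list(b$model$params),
                          r_squared = b$model$r_squared)
      } else {
        out$error <- b$error
      }
      out
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
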