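# Synthetic cross-sectional audiogram cohorts. Each subject contributes one
# binaural audiogram at one age; the threshold at each frequency follows a
# group-specific power law in age, a * age^b, plus additive homoskedastic
# Gaussian noise in dB, clipped to the audiometric range.

#' Specify a synthetic cross-sectional cohort
#'
#' @param n_subjects Number of subjects.
#' @param age_range `c(min, max)` years of the uniform age distribution;
#'   `min > 0`.
#' @param group_proportions Named fractions for `TBC` and `TLDc`, summing
#'   to 1.
#' @param curves Per-group generating curves: a named list
#'   `list(TBC = ..., TLDc = ...)`, each element a named list mapping
#'   frequency (Hz) to power-law parameters `c(a, b)` with `a > 0`.
#' @param noise_sd Additive Gaussian noise SD in dB (>= 0).
#' @param threshold_bounds `c(floor, ceiling)` in dB HL within \[-10, 120\];
#'   generated thresholds are clipped to this interval.
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects,
                        age_range = c(10, 75),
                        group_proportions = c(TBC = 0.5, TLDc = 0.5),
                        curves,
                        noise_sd = 3,
                        threshold_bounds = c(-10, 120),
                        seed = 1L) {
  problems <- character()
  if (length(n_subjects) != 1L || n_subjects < 1) {
    problems <- c(problems, "n_subjects must be a positive count")
  }
  if (length(age_range) != 2L || age_range[1] <= 0 ||
      age_range[1] >= age_range[2]) {
    problems <- c(problems, "age_range must be c(min, max) with 0 < min < max")
  }
  if (!setequal(names(group_proportions), c("TBC", "TLDc")) ||
      abs(sum(group_proportions) - 1) > 1e-9 || any(group_proportions < 0)) {
    problems <- c(problems,
                  "group_proportions must be named TBC/TLDc fractions summing to 1")
  }
  if (missing(curves) || !all(c("TBC", "TLDc") %in% names(curves))) {
    problems <- c(problems, "curves must supply a TBC and a TLDc curve set")
  } else {
    for (g in c("TBC", "TLDc")) {
      for (f in names(curves[[g]])) {
        pr <- curves[[g]][[f]]
        if (length(pr) != 2L || pr[1] <= 0) {
          problems <- c(problems,
                        sprintf("curve %s/%s Hz must be c(a, b) with a > 0", g, f))
        }
        if (!(as.integer(f) %in% canonical_frequencies())) {
          problems <- c(problems,
                        sprintf("curve frequency %s Hz is not canonical", f))
        }
      }
    }
  }
  if (length(noise_sd) != 1L || noise_sd < 0) {
    problems <- c(problems, "noise_sd must be a single value >= 0")
  }
  if (length(threshold_bounds) != 2L ||
      threshold_bounds[1] >= threshold_bounds[2] ||
      threshold_bounds[1] < -10 || threshold_bounds[2] > 120) {
    problems <- c(problems,
                  "threshold_bounds must be c(floor, ceiling) within [-10, 120]")
  }
  if (length(problems)) {
    ap_stop(paste0("invalid cohort spec:\n  - ",
                   paste(problems, collapse = "\n  - ")),
            "ap_validation_error")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         age_range = as.numeric(age_range),
         group_proportions = group_proportions[c("TBC", "TLDc")],
         curves = curves, noise_sd = noise_sd,
         threshold_bounds = as.numeric(threshold_bounds),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort
#'
#' Draws `n_subjects` binaural records: age uniform over the spec's range,
#' group from the spec's proportions, and each frequency's threshold from
#' the group's power-law curve plus Gaussian noise, clipped to the spec's
#' bounds. Fully reproducible from the spec's seed. The fraction of
#' thresholds that hit the clipping bounds is attached as attribute
#' `clipped_fraction` (0 for noiseless in-range curves).
#'
#' @param spec A [cohort_spec()].
#' @return List of `audiogram_record`s with attribute `clipped_fraction`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_subjects
    ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    groups <- sample(c("TBC", "TLDc"), n, replace = TRUE,
                     prob = spec$group_proportions)
    n_clip <- 0L
    n_thr <- 0L
    records <- lapply(seq_len(n), function(i) {
      cv <- spec$curves[[groups[i]]]
      freqs <- names(cv)
      mu <- vapply(cv, function(p) p[1] * ages[i]^p[2], numeric(1))
      y <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
      clipped <- y < spec$threshold_bounds[1] | y > spec$threshold_bounds[2]
      n_clip <<- n_clip + sum(clipped)
      n_thr <<- n_thr + length(y)
      y <- pmin(pmax(y, spec$threshold_bounds[1]), spec$threshold_bounds[2])
      audiogram_record(sprintf("SIM%04d", i), ages[i], "binaural",
                       stats::setNames(y, freqs), groups[i],
                       source = "synthetic")
    })
    attr(records, "clipped_fraction") <- n_clip / n_thr
    records
  })
}

#' Cohort spec emulating the TBC1D24 ADNSHL audioprofile
#'
#' A ready-made [cohort_spec()] whose band curves are the power laws through
#' the reported (25 dB, 60 dB) crossing-age pairs of TBC1D24-related
#' autosomal dominant hearing loss — low band 26.07/65.30 y, mid band
#' 22.70/41.17 y, high band 18.37/37.74 y — assigned to both member
#' frequencies of each band and shared by the two domain groups. With
#' `anchor_pta_onset` set, every PTA frequency (500-4000 Hz) instead shares
#' one curve (mid-band exponent) crossing 25 dB at that age, so the fitted
#' PTA onset is recoverable by construction.
#'
#' @param n_subjects Cohort size (default 60).
#' @param age_range Uniform age range in years (default `c(10, 65)`; the
#'   upper limit is chosen so all three band curves stay below the 120 dB
#'   audiometric ceiling across sampled ages, keeping noiseless cohorts
#'   exactly on their generating curves).
#' @param noise_sd Gaussian noise SD in dB (default 3; 0 for noiseless).
#' @param seed Integer seed.
#' @param anchor_pta_onset Optional onset age (years) to anchor the PTA
#'   curve at 25 dB; `NULL` (default) keeps the per-band curves.
#' @return A `cohort_spec`.
#' @export
tbc1d24_profile_spec <- function(n_subjects = 60, age_range = c(10, 65),
                                 noise_sd = 3, seed = 1L,
                                 anchor_pta_onset = NULL) {
  anchors <- list(
    low  = list(c(26.07, 25), c(65.30, 60)),
    mid  = list(c(22.70, 25), c(41.17, 60)),
    high = list(c(18.37, 25), c(37.74, 60))
  )
  band_models <- lapply(anchors, function(a)
    two_point_power_model(a[[1]], a[[2]]))
  curves <- list()
  for (bd in frequency_bands()) {
    m <- band_models[[bd$name]]
    for (f in bd$members) {
      curves[[as.character(f)]] <- unname(m$params)
    }
  }
  if (!is.null(anchor_pta_onset)) {
    b <- band_models$mid$params[["b"]]
    a <- 25 / anchor_pta_onset^b
    for (f in c("500", "1000", "2000", "4000")) curves[[f]] <- c(a, b)
  }
  cohort_spec(n_subjects = n_subjects, age_range = age_range,
              group_proportions = c(TBC = 0.5, TLDc = 0.5),
              curves = list(TBC = curves, TLDc = curves),
              noise_sd = noise_sd, seed = seed)
}

#' Read/write cohort specs as YAML
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `write_cohort_spec()` returns `path` invisibly;
#'   `read_cohort_spec()` returns a `cohort_spec`.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  obj <- unclass(spec)
  obj$group_proportions <- as.list(obj$group_proportions)
  obj$curves <- lapply(obj$curves, function(g)
    lapply(g, function(p) as.numeric(p)))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  cohort_spec(
    n_subjects = obj$n_subjects,
    age_range = unlist(obj$age_range),
    group_proportions = unlist(obj$group_proportions),
    curves = lapply(obj$curves, function(g) lapply(g, unlist)),
    noise_sd = obj$noise_sd,
    threshold_bounds = unlist(obj$threshold_bounds),
    seed = obj$seed
  )
}
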