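# Annual threshold deterioration (ATD): the cross-sectional rate of
# threshold worsening per year at one frequency, estimated as the pooled OLS
# slope of threshold on age, and compared between mutation-domain groups
# (TBC vs TLDc) with a seeded label-permutation test.

# slope of y on x via the normal equations; no lm() overhead because the
# permutation loop calls this tens of thousands of times
ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc * xc)
}

# slope plus its standard error in one pass
ols_slope_se <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x)
  sxx <- sum(xc * xc)
  slope <- sum(xc * y) / sxx
  yc <- y - mean(y)
  ss_res <- max(sum(yc * yc) - slope^2 * sxx, 0)
  c(slope = slope, se = sqrt(ss_res / (n - 2) / sxx))
}

atd_xy <- function(records, frequency) {
  key <- as.character(as.integer(frequency))
  thr <- vapply(records, function(r)
    if (key %in% names(r$thresholds)) r$thresholds[[key]] else NA_real_,
    numeric(1))
  ok <- !is.na(thr)
  list(age = vapply(records, `[[`, numeric(1), "age")[ok], thr = thr[ok])
}

#' Annual threshold deterioration at one frequency
#'
#' The slope, in dB/year, of the ordinary least-squares regression of
#' air-conduction threshold on age across records carrying `frequency`.
#'
#' @param records List of `audiogram_record`s.
#' @param frequency Frequency in Hz.
#' @return List with `atd` (dB/year) and `n` (records contributing).
#' @examples
#' recs <- lapply(1:3, function(i)
#'   audiogram_record(paste0("S", i), c(20, 30, 40)[i], "binaural",
#'                    stats::setNames(c(25, 35, 45)[i], 1000)))
#' annual_threshold_deterioration(recs, 1000)  # 1 dB/year, n = 3
#' @export
annual_threshold_deterioration <- function(records, frequency) {
  d <- atd_xy(records, frequency)
  if (length(d$age) < 3L) {
    ap_stop(sprintf("ATD at %g Hz needs >= 3 records, got %d",
                    frequency, length(d$age)),
            "ap_insufficient_data_error")
  }
  if (length(unique(d$age)) < 2L) {
    ap_stop(sprintf("ATD at %g Hz: all ages identical, slope undefined",
                    frequency),
            "ap_degenerate_design_error")
  }
  list(atd = ols_slope(d$age, d$thr), n = length(d$age))
}

#' Permutation comparison of ATD between two groups
#'
#' Tests whether the cross-sectional deterioration slopes of two groups
#' differ at one frequency. The reported `difference` is
#' slope(A) - slope(B); the test statistic is its studentized (Welch-type)
#' form, (slope(A) - slope(B)) / sqrt(se_A^2 + se_B^2), recomputed for each
#' relabeling so that groups of unequal residual variance are compared on a
#' common scale. The two-sided p-value comes from shuffling group labels
#' over subjects (`permutations` resamples under `seed`), with the add-one
#' correction (b + 1)/(B + 1). Subjects, not rows, are the permutation
#' unit, so a subject's records move between groups together.
#'
#' @param group_a,group_b Lists of `audiogram_record`s.
#' @param frequency Frequency in Hz.
#' @param permutations Number of label permutations (default 10000; fewer
#'   than 1000 draws a configuration warning).
#' @param seed Integer RNG seed; results are reproducible given the seed.
#' @return A `comparison_result`: `difference` (dB/year, A - B),
#'   `statistic`, `p_value`, `method`, `permutations`, `seed`, and per-group
#'   `atd_a`/`atd_b`/`n_a`/`n_b`.
#' @export
compare_atd <- function(group_a, group_b, frequency,
                        permutations = 10000L, seed = 1L) {
  permutations <- as.integer(permutations)
  if (permutations < 1000L) {
    ap_warn(sprintf(
      "only %d permutations; p-values reported from < 1000 resamples are noisy",
      permutations),
      "ap_configuration_warning")
  }
  a <- annual_threshold_deterioration(group_a, frequency)
  b <- annual_threshold_deterioration(group_b, frequency)
  obs <- a$atd - b$atd
  studentize <- function(in_a, x, y) {
    sa <- ols_slope_se(x[in_a], y[in_a])
    sb <- ols_slope_se(x[!in_a], y[!in_a])
    (sa[["slope"]] - sb[["slope"]]) /
      sqrt(sa[["se"]]^2 + sb[["se"]]^2)
  }

  # pool subjects, then permute the subject -> group assignment keeping the
  # group sizes fixed; when a subject id is reused across groups the unit
  # key carries the origin group so the two occurrences stay distinct
  pooled <- c(group_a, group_b)
  ids <- vapply(pooled, `[[`, character(1), "subject_id")
  in_b <- seq_along(pooled) > length(group_a)
  if (length(intersect(ids[!in_b], ids[in_b]))) {
    subj <- paste(ifelse(in_b, "B", "A"), ids, sep = ":")
  } else {
    subj <- ids
  }
  usubj <- sort(unique(subj))
  n_subj_a <- length(unique(subj[!in_b]))
  xy <- atd_xy(pooled, frequency)
  has_f <- vapply(pooled, function(r)
    as.character(as.integer(frequency)) %in% names(r$thresholds), logical(1))
  subj_f <- subj[has_f]

  obs_in_a <- subj_f %in% subj[!in_b]
  t_obs <- studentize(obs_in_a, xy$age, xy$thr)

  perm_stats <- with_seed(seed, {
    vapply(seq_len(permutations), function(i) {
      lab_a <- sample(usubj, n_subj_a)
      in_a <- subj_f %in% lab_a
      if (sum(in_a) < 3L || sum(!in_a) < 3L ||
          length(unique(xy$age[in_a])) < 2L ||
          length(unique(xy$age[!in_a])) < 2L) {
        return(NA_real_)
      }
      studentize(in_a, xy$age, xy$thr)
    }, numeric(1))
  })
  perm_stats <- perm_stats[is.finite(perm_stats)]
  b_exceed <- sum(abs(perm_stats) >= abs(t_obs))
  p <- (b_exceed + 1) / (length(perm_stats) + 1)

  structure(
    list(difference = obs, statistic = t_obs, p_value = p,
         method = "two-sided studentized label-permutation test of OLS slope difference",
         permutations = permutations, seed = as.integer(seed),
         atd_a = a$atd, atd_b = b$atd, n_a = a$n, n_b = b$n),
    class = "comparison_result"
  )
}

#' Per-frequency ATD table with group comparison
#'
#' One row per canonical frequency (250-8000 Hz): the TBC and TLDc group
#' ATDs with their n, the slope difference, and the permutation p-value. A
#' frequency at which either group fails the ATD preconditions is skipped
#' with a warning. A supplementary Bonferroni-adjusted p-value column is
#' emitted; the primary per-frequency p-values are uncorrected.
#'
#' @param records List of `audiogram_record`s carrying TBC/TLDc labels.
#' @param frequencies Frequencies to tabulate; default 250-8000 Hz.
#' @param permutations Permutations per frequency (default 10000).
#' @param seed Integer seed; the table is deterministic given the seed
#'   (each frequency uses a sub-seed derived from it).
#' @return An `atd_table` data frame with columns `freq_hz`, `atd_tbc`,
#'   `n_tbc`, `atd_tldc`, `n_tldc`, `difference`, `p_value`, `p_bonferroni`,
#'   `permutations`, `seed`.
#' @export
atd_table <- function(records, frequencies = c(250L, 500L, 1000L, 2000L,
                                               4000L, 8000L),
                      permutations = 10000L, seed = 1L) {
  grp <- vapply(records, `[[`, character(1), "group")
  tbc <- records[grp == "TBC"]
  tldc <- records[grp == "TLDc"]
  if (length(tbc) == 0L || length(tldc) == 0L) {
    ap_stop(sprintf(
      "both groups required for the ATD comparison (TBC n=%d, TLDc n=%d)",
      length(tbc), length(tldc)),
      "ap_stratification_error")
  }
  rows <- lapply(seq_along(frequencies), function(i) {
    f <- frequencies[i]
    tryCatch({
      cmp <- compare_atd(tbc, tldc, f, permutations = permutations,
                         seed = as.integer(seed) + i - 1L)
      data.frame(freq_hz = as.integer(f),
                 atd_tbc = cmp$atd_a, n_tbc = cmp$n_a,
                 atd_tldc = cmp$atd_b, n_tldc = cmp$n_b,
                 difference = cmp$difference, p_value = cmp$p_value,
                 permutations = cmp$permutations, seed = cmp$seed)
    }, ap_error = function(e) {
      ap_warn(sprintf("frequency %g Hz skipped: %s", f, conditionMessage(e)),
              "ap_frequency_skipped_warning")
      NULL
    })
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    ap_stop("no frequency met the ATD preconditions in both groups",
            "ap_insufficient_data_error")
  }
  out$p_bonferroni <- pmin(1, out$p_value * nrow(out))
  out <- out[, c("freq_hz", "atd_tbc", "n_tbc", "atd_tldc", "n_tldc",
                 "difference", "p_value", "p_bonferroni", "permutations",
                 "seed")]
  class(out) <- c("atd_table", "data.frame")
  out
}

#' Write an ATD table in the wide two-group layout
#'
#' CSV with one column per frequency (in kHz) and rows for each group's ATD
#' and the p-value — the layout audiometric genotype-phenotype reports use.
#'
#' @param x An `atd_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_atd_wide <- function(x, path) {
  stopifnot(inherits(x, "atd_table"))
  wide <- data.frame(
    row = c("TBC", "TLDc", "p-value"),
    rbind(x$atd_tbc, x$atd_tldc, x$p_value)
  )
  names(wide) <- c("row", paste0(x$freq_hz / 1000, " kHz"))
  utils::write.csv(wide, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serialize an ATD table to JSON with full metadata
#'
#' @param x An `atd_table`.
#' @param path Optional output file.
#' @return JSON string (invisibly if written to `path`).
#' @export
atd_table_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "atd_table"))
  obj <- list(
    method = "two-sided studentized label-permutation test of OLS slope difference",
    rows = lapply(seq_len(nrow(x)), function(i) as.list(x[i, , drop = FALSE]))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
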