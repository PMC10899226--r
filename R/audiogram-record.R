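# Audiogram data model: one record per subject/ear at a known age, with a
# named threshold map over the canonical audiometric frequencies.

#' Canonical audiometric frequencies (Hz)
#'
#' The octave frequencies a clinical pure-tone audiogram reports. 125 Hz is
#' accepted on input but used by no downstream analysis (neither the PTA nor
#' the frequency bands reference it).
#'
#' @return Integer vector of frequencies in Hz.
#' @export
canonical_frequencies <- function() {
  c(125L, 250L, 500L, 1000L, 2000L, 4000L, 8000L)
}

#' Standard low/mid/high frequency bands
#'
#' Low = 250/500 Hz, mid = 1000/2000 Hz, high = 4000/8000 Hz; the disjoint
#' bands over which per-band progression curves are fitted.
#'
#' @return Named list of `frequency_band` objects.
#' @export
frequency_bands <- function() {
  list(
    low  = frequency_band("low",  c(250L, 500L)),
    mid  = frequency_band("mid",  c(1000L, 2000L)),
    high = frequency_band("high", c(4000L, 8000L))
  )
}

#' Construct a frequency band
#'
#' @param name Band name, one of `"low"`, `"mid"`, `"high"`.
#' @param members Ordered integer vector of member frequencies (Hz), drawn
#'   from [canonical_frequencies()].
#' @return A `frequency_band` object.
#' @export
frequency_band <- function(name, members) {
  name <- match.arg(name, c("low", "mid", "high"))
  members <- as.integer(members)
  if (!all(members %in% canonical_frequencies())) {
    ap_stop("band members must be canonical audiometric frequencies",
            "ap_validation_error")
  }
  structure(list(name = name, members = members), class = "frequency_band")
}

#' Construct an audiogram record
#'
#' One subject's air-conduction thresholds across frequencies at one age.
#' Thresholds are canonicalized to ascending frequency order.
#'
#' @param subject_id Opaque subject identifier (character scalar).
#' @param age Age in years (> 0).
#' @param ear `"left"`, `"right"`, or `"binaural"`.
#' @param thresholds Named numeric vector: names are frequencies in Hz (from
#'   the canonical set), values air-conduction thresholds in dB HL, each in
#'   \[-10, 120\].
#' @param group Mutation-domain group: `"TBC"`, `"TLDc"`, or `"unknown"`.
#' @param source Free-text provenance tag.
#' @return An `audiogram_record` object.
#' @examples
#' audiogram_record("S1", 30, "binaural",
#'                  c(`500` = 20, `1000` = 30, `2000` = 40, `4000` = 50))
#' @export
audiogram_record <- function(subject_id, age, ear,
                             thresholds, group = "unknown", source = "") {
  subject_id <- as.character(subject_id)
  age <- as.numeric(age)
  ear <- match.arg(ear, c("left", "right", "binaural"))
  group <- match.arg(group, c("TBC", "TLDc", "unknown"))
  if (length(age) != 1L || is.na(age) || age <= 0) {
    ap_stop("age must be a single positive number of years",
            "ap_validation_error")
  }
  thresholds <- unlist(thresholds)
  freqs <- suppressWarnings(as.integer(names(thresholds)))
  if (length(thresholds) == 0L || anyNA(freqs)) {
    ap_stop("thresholds must be a named numeric vector keyed by frequency (Hz)",
            "ap_validation_error")
  }
  bad_f <- setdiff(freqs, canonical_frequencies())
  if (length(bad_f)) {
    ap_stop(sprintf("non-canonical frequency key(s): %s",
                    paste(bad_f, collapse = ", ")),
            "ap_validation_error")
  }
  if (anyDuplicated(freqs)) {
    ap_stop("duplicate frequency keys in thresholds", "ap_validation_error")
  }
  vals <- as.numeric(thresholds)
  if (anyNA(vals) || any(vals < -10 | vals > 120)) {
    ap_stop("thresholds must be numeric in [-10, 120] dB HL",
            "ap_validation_error")
  }
  ord <- order(freqs)
  thr <- stats::setNames(vals[ord], as.character(freqs[ord]))
  structure(
    list(subject_id = subject_id, age = age, ear = ear,
         thresholds = thr, group = group, source = as.character(source)),
    class = "audiogram_record"
  )
}

#' @export
print.audiogram_record <- function(x, ...) {
  cat(sprintf("<audiogram_record> %s (%s, %.1f y, %s)\n",
              x$subject_id, x$ear, x$age, x$group))
  print(x$thresholds)
  invisible(x)
}

#' Binaural average of a left/right record pair
#'
#' For each frequency present in both ears, the binaural threshold is the
#' arithmetic mean; a frequency present in only one ear carries that ear's
#' value, with a warning.
#'
#' @param left,right `audiogram_record`s for the same subject at the same
#'   age, ears left and right (in either argument order).
#' @return A binaural `audiogram_record`.
#' @export
binaural_average <- function(left, right) {
  stopifnot(inherits(left, "audiogram_record"),
            inherits(right, "audiogram_record"))
  if (left$subject_id != right$subject_id) {
    ap_stop(sprintf("cannot pair ears of different subjects ('%s' vs '%s')",
                    left$subject_id, right$subject_id),
            "ap_pairing_error")
  }
  if (!isTRUE(all.equal(left$age, right$age))) {
    ap_stop(sprintf("subject '%s': left/right ages differ (%g vs %g)",
                    left$subject_id, left$age, right$age),
            "ap_pairing_error")
  }
  ears <- sort(c(left$ear, right$ear))
  if (!identical(ears, c("left", "right"))) {
    ap_stop("binaural_average needs one left and one right record",
            "ap_pairing_error")
  }
  all_f <- sort(unique(c(names(left$thresholds), names(right$thresholds))))
  thr <- vapply(all_f, function(f) {
    a <- left$thresholds[f]
    b <- right$thresholds[f]
    if (is.na(a)) b else if (is.na(b)) a else (a + b) / 2
  }, numeric(1))
  only_one <- all_f[is.na(left$thresholds[all_f]) |
                      is.na(right$thresholds[all_f])]
  if (length(only_one)) {
    ap_warn(sprintf(
      "subject '%s': only one ear measured at %s Hz; single-ear value carried",
      left$subject_id, paste(only_one, collapse = ", ")),
      "ap_single_ear_warning")
  }
  grp <- if (left$group == right$group) left$group else "unknown"
  audiogram_record(left$subject_id, left$age, "binaural",
                   stats::setNames(thr, all_f), grp, left$source)
}

#' Pure-tone average (PTA)
#'
#' Arithmetic mean of the air-conduction thresholds at 500, 1000, 2000 and
#' 4000 Hz — the scalar hearing summary regressed on age. All four
#' constituent frequencies are required: the PTA is the regression response
#' and must be comparable across subjects.
#'
#' @param record An `audiogram_record`.
#' @param frequencies Constituent frequencies (Hz); default 500/1000/2000/4000.
#' @return PTA in dB HL.
#' @examples
#' r <- audiogram_record("S1", 40, "binaural",
#'                       c(`500` = 20, `1000` = 30, `2000` = 40, `4000` = 50))
#' compute_pta(r)  # 35
#' @export
compute_pta <- function(record, frequencies = c(500L, 1000L, 2000L, 4000L)) {
  stopifnot(inherits(record, "audiogram_record"))
  keys <- as.character(frequencies)
  missing_f <- keys[!keys %in% names(record$thresholds)]
  if (length(missing_f)) {
    ap_stop(sprintf("subject '%s': PTA needs %s Hz; missing: %s",
                    record$subject_id, paste(frequencies, collapse = "/"),
                    paste(missing_f, collapse = ", ")),
            "ap_incomplete_audiogram_error")
  }
  mean(record$thresholds[keys])
}

#' Mean threshold over a frequency band
#'
#' Arithmetic mean over the band members present in the record. If only one
#' member is present its value is returned with a warning; if none is
#' present an incomplete-audiogram error is raised.
#'
#' @param record An `audiogram_record`.
#' @param band A `frequency_band`.
#' @return Band mean threshold in dB HL.
#' @export
band_mean <- function(record, band) {
  stopifnot(inherits(record, "audiogram_record"),
            inherits(band, "frequency_band"))
  keys <- as.character(band$members)
  present <- keys[keys %in% names(record$thresholds)]
  if (length(present) == 0L) {
    ap_stop(sprintf("subject '%s': no %s-band frequency (%s Hz) present",
                    record$subject_id, band$name,
                    paste(band$members, collapse = "/")),
            "ap_incomplete_audiogram_error")
  }
  if (length(present) < length(keys)) {
    ap_warn(sprintf("subject '%s': %s-band mean from %d of %d members",
                    record$subject_id, band$name,
                    length(present), length(keys)),
            "ap_partial_band_warning")
  }
  mean(record$thresholds[present])
}

#' WHO (1997) hearing-impairment grades
#'
#' Upper PTA cutoffs (dB HL) for each grade: normal <= 25, mild 26-40,
#' moderate 41-60, severe 61-80, profound >= 81.
#'
#' @return Named numeric vector of upper cutoffs (profound is `Inf`).
#' @export
who_1997_grades <- function() {
  c(normal = 25, mild = 40, moderate = 60, severe = 80, profound = Inf)
}

#' Classify hearing-loss severity from a PTA
#'
#' @param pta Pure-tone average(s) in dB HL, each in \[-10, 120\].
#' @param grades Named vector of upper cutoffs per grade, ascending;
#'   default [who_1997_grades()].
#' @return Character vector of grades.
#' @examples
#' classify_severity(c(10, 50, 95))  # normal, moderate, profound
#' @export
classify_severity <- function(pta, grades = who_1997_grades()) {
  if (any(is.na(pta)) || any(pta < -10 | pta > 120)) {
    ap_stop("PTA out of the audiometric domain [-10, 120] dB HL",
            "ap_domain_error")
  }
  vapply(pta, function(p) names(grades)[which(p <= grades)[1L]], character(1))
}
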