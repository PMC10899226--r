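# Fixture builders shared across test files. All randomness is seeded at the
# call site so every test is reproducible in isolation.

options(audioprog.quiet = TRUE)

full_thresholds <- function(values) {
  stats::setNames(values, c(125, 250, 500, 1000, 2000, 4000, 8000))
}

make_record <- function(id = "S1", age = 30, ear = "binaural",
                        thresholds = full_thresholds(rep(40, 7)),
                        group = "unknown") {
  audiogram_record(id, age, ear, thresholds, group)
}

# n random well-formed records on realistic audiometric grids (ages to two
# decimals, thresholds in 0.5 dB steps) so CSV round trips are exact
random_records <- function(n, seed = 1, group = "unknown") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    freqs <- sort(sample(canonical_frequencies(),
                         sample(4:7, 1)))
    audiogram_record(
      sprintf("R%03d", i),
      round(runif(1, 5, 80), 2),
      sample(c("left", "right", "binaural"), 1),
      stats::setNames(round(runif(length(freqs), -10, 120) * 2) / 2, freqs),
      group = if (is.null(group)) sample(c("TBC", "TLDc"), 1) else group
    )
  })
}

# cross-sectional records at one frequency whose thresholds follow
# intercept + slope*age + N(0, sd); used by the ATD tests
slope_records <- function(n, slope, frequency = 2000, intercept = 10,
                          sd = 1, seed = 1, prefix = "S",
                          group = "unknown", age_range = c(10, 70)) {
  set.seed(seed)
  ages <- runif(n, age_range[1], age_range[2])
  thr <- pmin(pmax(intercept + slope * ages + rnorm(n, 0, sd), -10), 120)
  lapply(seq_len(n), function(i) {
    audiogram_record(sprintf("%s%03d", prefix, i), ages[i], "binaural",
                     stats::setNames(thr[i], frequency), group)
  })
}
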