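# Annual threshold deterioration and the permutation group comparison.

test_that("ATD equals the OLS slope of threshold on age", {
  recs <- lapply(1:3, function(i)
    audiogram_record(paste0("S", i), c(20, 30, 40)[i], "binaural",
                     stats::setNames(c(25, 35, 45)[i], 1000)))
  out <- annual_threshold_deterioration(recs, 1000)
  expect_equal(out$atd, 1.0, tolerance = 1e-12)
  expect_identical(out$n, 3L)

  flat <- lapply(1:4, function(i)
    audiogram_record(paste0("F", i), 10 * i, "binaural",
                     stats::setNames(30, 2000)))
  expect_equal(annual_threshold_deterioration(flat, 2000)$atd, 0)

  # oracle: lm() on 100 seeded random records
  recs <- slope_records(100, slope = 0.6, sd = 4, seed = 3)
  ages <- vapply(recs, `[[`, numeric(1), "age")
  thr <- vapply(recs, function(r) r$thresholds[["2000"]], numeric(1))
  expect_equal(annual_threshold_deterioration(recs, 2000)$atd,
               unname(coef(lm(thr ~ ages))[2]), tolerance = 1e-10)

  # record order does not matter; a point on the fitted line changes nothing
  set.seed(1)
  expect_equal(annual_threshold_deterioration(sample(recs), 2000)$atd,
               annual_threshold_deterioration(recs, 2000)$atd,
               tolerance = 1e-12)
  fit <- lm(thr ~ ages)
  on_line <- audiogram_record("X1", 50, "binaural",
                              stats::setNames(unname(predict(fit,
                                data.frame(ages = 50))), 2000))
  expect_equal(annual_threshold_deterioration(c(recs, list(on_line)),
                                              2000)$atd,
               annual_threshold_deterioration(recs, 2000)$atd,
               tolerance = 1e-10)
})

test_that("ATD preconditions reject tiny or degenerate designs", {
  two <- slope_records(2, slope = 1, seed = 1)
  expect_error(annual_threshold_deterioration(two, 2000),
               class = "ap_insufficient_data_error")
  same_age <- lapply(1:5, function(i)
    audiogram_record(paste0("A", i), 30, "binaural",
                     stats::setNames(20 + i, 2000)))
  expect_error(annual_threshold_deterioration(same_age, 2000),
               class = "ap_degenerate_design_error")
})

test_that("an exchangeable null gives difference 0 and a large p-value", {
  grp <- slope_records(25, slope = 0.5, sd = 2, seed = 8, prefix = "N")
  cmp <- compare_atd(grp, grp, 2000, permutations = 2000, seed = 4)
  expect_equal(cmp$difference, 0, tolerance = 1e-12)
  expect_gt(cmp$p_value, 0.5)
})

test_that("a large slope separation is detected", {
  # ages capped at 50 y so the steep group stays below the 120 dB ceiling
  a <- slope_records(30, slope = 2.0, sd = 1, seed = 21, prefix = "A",
                     age_range = c(10, 50))
  b <- slope_records(30, slope = 0.1, sd = 1, seed = 22, prefix = "B",
                     age_range = c(10, 50))
  cmp <- compare_atd(a, b, 2000, permutations = 2000, seed = 5)
  expect_gt(cmp$difference, 1.5)
  expect_lt(cmp$p_value, 0.01)
})

test_that("permutation p-values are seed-reproducible and seed-consistent", {
  a <- slope_records(30, slope = 0.8, sd = 6, seed = 31, prefix = "A")
  b <- slope_records(30, slope = 0.4, sd = 6, seed = 32, prefix = "B")
  p1 <- compare_atd(a, b, 2000, permutations = 2000, seed = 7)
  p2 <- compare_atd(a, b, 2000, permutations = 2000, seed = 7)
  expect_identical(p1, p2)

  # across seeds: agreement within Monte-Carlo error (+/- 2 sqrt(p(1-p)/B))
  others <- vapply(8:10, function(s)
    compare_atd(a, b, 2000, permutations = 2000, seed = s)$p_value,
    numeric(1))
  mc <- 2 * sqrt(p1$p_value * (1 - p1$p_value) / 2000)
  expect_true(all(abs(others - p1$p_value) < mc + 1e-9))
})

test_that("fewer than 1000 permutations draws a configuration warning", {
  a <- slope_records(10, slope = 1, seed = 41, prefix = "A")
  b <- slope_records(10, slope = 1, seed = 42, prefix = "B")
  expect_warning(compare_atd(a, b, 2000, permutations = 200, seed = 1),
                 class = "ap_configuration_warning")
})

test_that("atd_table recovers generating slopes and is deterministic", {
  # b = 1 power curves make the generating slope exactly the parameter a
  curves <- function(s250, s2000) list(
    `250` = c(s250, 1), `2000` = c(s2000, 1))
  spec <- cohort_spec(
    n_subjects = 120, age_range = c(10, 70),
    curves = list(TBC = curves(0.7, 0.75), TLDc = curves(0.7, 0.10)),
    noise_sd = 4, seed = 12)
  co <- generate_cohort(spec)
  tab <- atd_table(co, frequencies = c(250, 2000),
                   permutations = 2000, seed = 3)

  group_cols <- c(tbc = "TBC", tldc = "TLDc")
  for (i in seq_len(nrow(tab))) {
    for (g in names(group_cols)) {
      gname <- group_cols[[g]]
      sub_recs <- co[vapply(co, `[[`, character(1), "group") == gname]
      ages <- vapply(sub_recs, `[[`, numeric(1), "age")
      thr <- vapply(sub_recs, function(r)
        r$thresholds[[as.character(tab$freq_hz[i])]], numeric(1))
      se <- summary(lm(thr ~ ages))$coefficients[2, 2]
      gen <- spec$curves[[gname]][[as.character(tab$freq_hz[i])]][1]
      expect_lt(abs(tab[[paste0("atd_", g)]][i] - gen), 2 * se)
    }
  }
  # the shared 250 Hz slope is not flagged; the separated 2000 Hz slope is
  expect_gt(tab$p_value[tab$freq_hz == 250], 0.05)
  expect_lt(tab$p_value[tab$freq_hz == 2000], 0.01)
  expect_equal(tab$n_tbc + tab$n_tldc, rep(120L, 2L),
               ignore_attr = TRUE)

  expect_identical(tab, atd_table(co, frequencies = c(250, 2000),
                                  permutations = 2000, seed = 3))
})

test_that("relabeling the groups swaps columns, negates differences, keeps p", {
  a <- slope_records(20, slope = 1.2, sd = 3, seed = 51, prefix = "A",
                     group = "TBC")
  b <- slope_records(20, slope = 0.3, sd = 3, seed = 52, prefix = "B",
                     group = "TLDc")
  tab <- atd_table(c(a, b), frequencies = 2000, permutations = 2000,
                   seed = 2)
  flip <- function(r) { r$group <- if (r$group == "TBC") "TLDc" else "TBC"; r }
  tab_swapped <- atd_table(c(lapply(a, flip), lapply(b, flip)),
                           frequencies = 2000, permutations = 2000, seed = 2)
  expect_equal(tab_swapped$atd_tbc, tab$atd_tldc)
  expect_equal(tab_swapped$atd_tldc, tab$atd_tbc)
  expect_equal(tab_swapped$difference, -tab$difference)
  expect_equal(tab_swapped$p_value, tab$p_value)
})

test_that("a missing group is a stratification error", {
  only_tbc <- slope_records(10, slope = 1, seed = 61, group = "TBC")
  expect_error(atd_table(only_tbc), class = "ap_stratification_error")
})

test_that("the wide table layout has group rows and kHz columns", {
  a <- slope_records(15, slope = 1.0, sd = 2, seed = 71, prefix = "A",
                     group = "TBC", frequency = 2000)
  b <- slope_records(15, slope = 0.5, sd = 2, seed = 72, prefix = "B",
                     group = "TLDc", frequency = 2000)
  tab <- atd_table(c(a, b), frequencies = 2000, permutations = 1000, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_atd_wide(tab, path)
  wide <- read.csv(path, check.names = FALSE)
  expect_identical(wide$row, c("TBC", "TLDc", "p-value"))
  expect_identical(names(wide), c("row", "2 kHz"))
})
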