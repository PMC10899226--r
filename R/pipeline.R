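# End-to-end orchestration: load -> binaural average -> PTA/band means ->
# model fitting and selection -> onset/HPT -> ATD group comparison, with
# partial failures reported in place rather than aborting the run.

#' Pipeline configuration
#'
#' Defaults reproduce the standard analysis definitions exactly: onset at
#' the 25 dB crossing, progression to 60 dB, PTA over 500/1000/2000/4000 Hz,
#' the low/mid/high bands, all four candidate families, 10,000 permutations.
#'
#' @param input Path to an audiogram CSV (see [read_audiogram_table()]).
#' @param onset_level Onset crossing level in dB HL (default 25).
#' @param progression_level Progression crossing level in dB HL (default 60);
#'   must exceed `onset_level`.
#' @param pta_frequencies PTA constituent frequencies (Hz).
#' @param bands List of `frequency_band`s.
#' @param model_families Families entered into the PTA model comparison.
#' @param permutations ATD permutation count.
#' @param seed Integer seed for the ATD permutation test.
#' @param out_dir Optional output directory for rendered reports.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input,
                            onset_level = 25,
                            progression_level = 60,
                            pta_frequencies = c(500L, 1000L, 2000L, 4000L),
                            bands = frequency_bands(),
                            model_families = audioprog::model_families(),
                            permutations = 10000L,
                            seed = 1L,
                            out_dir = NULL) {
  if (!(onset_level < progression_level)) {
    ap_stop("onset_level must be below progression_level",
            "ap_validation_error")
  }
  structure(
    list(input = input, onset_level = onset_level,
         progression_level = progression_level,
         pta_frequencies = as.integer(pta_frequencies),
         bands = bands, model_families = model_families,
         permutations = as.integer(permutations), seed = as.integer(seed),
         out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full audiometric progression pipeline
#'
#' Executes the analysis stages in order: read the cohort, collapse per-ear
#' pairs to binaural records, compute PTA and band means, fit and compare
#' the candidate threshold-age models, invert the selected model for onset
#' age and the per-band power fits for crossing ages and HPT, then build the
#' per-frequency ATD table with the TBC-vs-TLDc permutation comparison. A
#' stage that cannot run (e.g. a single-group cohort has no ATD comparison)
#' is reported in place without aborting the run.
#'
#' @param config A [pipeline_config()].
#' @return An `analysis_report`: `progression` (a `progression_summary`),
#'   `atd` (an `atd_table`, or `NULL` with `atd_error` set), `status`
#'   (`"complete"` or `"partial"`), and `provenance` (config echo, seed,
#'   package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  records <- read_audiogram_table(config$input)
  if (length(records) == 0L) {
    ap_stop("input parses to an empty cohort", "ap_insufficient_data_error")
  }
  records <- collapse_binaural(records)
  ap_log(sprintf("loaded %d binaural record(s) from %s",
                 length(records), config$input))

  progression <- progression_summary(
    records, bands = config$bands, families = config$model_families,
    onset_level = config$onset_level,
    progression_level = config$progression_level)

  atd_error <- NULL
  atd <- tryCatch(
    atd_table(records, permutations = config$permutations,
              seed = config$seed),
    ap_error = function(e) {
      atd_error <<- conditionMessage(e)
      ap_log("ATD comparison unavailable: ", conditionMessage(e))
      NULL
    })

  band_failed <- any(vapply(progression$bands,
                            function(b) !is.null(b$error), logical(1)))
  status <- if (is.null(atd) || band_failed) "partial" else "complete"

  structure(
    list(progression = progression, atd = atd, atd_error = atd_error,
         status = status,
         provenance = list(
           input = config$input,
           onset_level = config$onset_level,
           progression_level = config$progression_level,
           pta_frequencies = config$pta_frequencies,
           permutations = config$permutations,
           seed = config$seed,
           package_version = as.character(utils::packageVersion("audioprog")))),
    class = "analysis_report"
  )
}

report_as_list <- function(report) {
  pg <- report$progression
  list(
    status = report$status,
    progression = list(
      onset_age_years = pg$onset_age,
      selected_family = pg$selected_family,
      n_subjects = pg$n_subjects,
      model_comparison = pg$model_comparison,
      bands = lapply(unname(pg$bands), function(b) {
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
    ),
    atd = if (!is.null(report$atd)) {
      lapply(seq_len(nrow(report$atd)), function(i)
        as.list(as.data.frame(report$atd)[i, , drop = FALSE]))
    } else {
      list(error = report$atd_error)
    },
    provenance = report$provenance
  )
}

#' Render an analysis report
#'
#' `"json"` is lossless (and byte-identical across runs with the same
#' inputs and seed); `"csv"` writes the per-band progression rows and the
#' wide two-group ATD block; `"text"` is a human-readable summary with
#' 2-decimal rounding.
#'
#' @param report An `analysis_report` from [run_pipeline()].
#' @param format `"json"`, `"csv"` or `"text"`.
#' @param path Output file path (for `"csv"`, a path prefix: writes
#'   `<path>_bands.csv` and `<path>_atd.csv`). When `NULL`, the rendering is
#'   returned as a character value.
#' @return The rendered artifact (invisibly when written to `path`).
#' @export
render_report <- function(report, format = c("json", "csv", "text"),
                          path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  format <- match.arg(format)
  if (format == "json") {
    js <- jsonlite::toJSON(report_as_list(report), auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null",
                           pretty = TRUE)
    if (!is.null(path)) {
      writeLines(js, path)
      return(invisible(js))
    }
    return(js)
  }
  if (format == "csv") {
    pg <- report$progression
    bands_df <- do.call(rbind, lapply(pg$bands, function(b)
      data.frame(band = b$name, age_25db = b$age_25, age_60db = b$age_60,
                 hpt_years = b$hpt, extrapolated = b$extrapolated,
                 r_squared = if (is.null(b$model)) NA_real_
                             else b$model$r_squared)))
    if (is.null(path)) {
      con <- textConnection("out", "w", local = TRUE)
      utils::write.csv(bands_df, con, row.names = FALSE)
      close(con)
      return(paste(out, collapse = "\n"))
    }
    utils::write.csv(bands_df, paste0(path, "_bands.csv"), row.names = FALSE)
    if (!is.null(report$atd)) {
      write_atd_wide(report$atd, paste0(path, "_atd.csv"))
    }
    return(invisible(path))
  }
  # text
  pg <- report$progression
  lines <- c(
    sprintf("Audiometric progression report (%s)", report$status),
    sprintf("  subjects: %d | selected model: %s",
            pg$n_subjects, pg$selected_family),
    sprintf("  onset age (%g dB crossing): %s years", pg$onset_level,
            if (is.na(pg$onset_age)) "not attained"
            else sprintf("%.2f", pg$onset_age)),
    unlist(lapply(pg$bands, function(b) {
      if (is.null(b$error)) {
        sprintf("  %s band: %g dB at %.2f y, %g dB at %.2f y, HPT %.2f y%s",
                b$name, pg$onset_level, b$age_25, pg$progression_level,
                b$age_60, b$hpt,
                if (isTRUE(b$extrapolated)) " [extrapolated]" else "")
      } else {
        sprintf("  %s band: unavailable (%s)", b$name, b$error)
      }
    })),
    if (!is.null(report$atd)) {
      c("  ATD (dB/year) and permutation p-values:",
        sprintf("    %g Hz: TBC %.4f (n=%d) vs TLDc %.4f (n=%d), p = %.4f",
                report$atd$freq_hz, report$atd$atd_tbc, report$atd$n_tbc,
                report$atd$atd_tldc, report$atd$n_tldc, report$atd$p_value))
    } else {
      sprintf("  ATD comparison unavailable: %s", report$atd_error)
    }
  )
  txt <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
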