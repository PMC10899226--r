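# Delimited-text reader/writer for audiogram cohorts.
#
# Table schema (long/tidy CSV, UTF-8, header required): one row per
# subject/ear/frequency with columns subject_id, age_years, ear, freq_hz,
# threshold_db, group, and optional source.

REQUIRED_COLUMNS <- c("subject_id", "age_years", "ear",
                      "freq_hz", "threshold_db", "group")

#' Read an audiogram table
#'
#' Parses a long-format CSV (one row per subject/ear/frequency) into a list
#' of [audiogram_record()]s, merging rows for the same (subject, ear, age)
#' into one thresholds map. Rows violating the record invariants are rejected
#' with row-level diagnostics. If a subject supplies a binaural record, any
#' per-ear records for that subject are dropped (with a warning) to avoid
#' double counting.
#'
#' @param path Path to a CSV file with columns `subject_id`, `age_years`,
#'   `ear`, `freq_hz`, `threshold_db`, `group` and optionally `source`.
#' @param sep Field separator (default `","`).
#' @return List of `audiogram_record` objects, in first-appearance order.
#' @seealso [write_audiogram_table()]
#' @export
read_audiogram_table <- function(path, sep = ",") {
  if (!file.exists(path)) {
    ap_stop(sprintf("input file not found: %s", path), "ap_io_error")
  }
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols)) {
    ap_stop(sprintf("missing required column(s): %s",
                    paste(missing_cols, collapse = ", ")),
            "ap_schema_error")
  }
  if (nrow(df) == 0L) {
    ap_warn(sprintf("'%s': header only, no data rows", path),
            "ap_empty_table_warning")
    return(list())
  }
  if (!"source" %in% names(df)) df$source <- ""
  df$source[is.na(df$source)] <- ""

  row_no <- seq_len(nrow(df)) + 1L  # file line numbers (header = line 1)
  age <- suppressWarnings(as.numeric(df$age_years))
  thr <- suppressWarnings(as.numeric(df$threshold_db))
  frq <- suppressWarnings(as.integer(df$freq_hz))
  bad <- which(is.na(age) | is.na(thr) | is.na(frq))
  if (length(bad)) {
    ap_stop(sprintf("non-numeric age/threshold/frequency at row(s): %s",
                    paste(row_no[bad], collapse = ", ")),
            "ap_parse_error")
  }

  # duplicate (subject, ear, freq) rows: identical values merge silently,
  # conflicting values are an error naming the rows involved
  key3 <- paste(df$subject_id, df$ear, age, frq, sep = "\r")
  if (anyDuplicated(key3)) {
    for (k in unique(key3[duplicated(key3)])) {
      i <- which(key3 == k)
      if (length(unique(thr[i])) > 1L) {
        ap_stop(sprintf(
          "conflicting duplicate thresholds for subject '%s' (%s, %s Hz) at rows %s",
          df$subject_id[i[1]], df$ear[i[1]], frq[i[1]],
          paste(row_no[i], collapse = ", ")),
          "ap_conflict_error")
      }
    }
    keep <- !duplicated(key3)
    df <- df[keep, , drop = FALSE]
    age <- age[keep]; thr <- thr[keep]; frq <- frq[keep]; row_no <- row_no[keep]
  }

  rec_key <- paste(df$subject_id, df$ear, age, sep = "\r")
  records <- list()
  for (k in unique(rec_key)) {
    i <- which(rec_key == k)
    grp <- unique(df$group[i])
    if (length(grp) > 1L) {
      ap_stop(sprintf("inconsistent group labels for subject '%s' at rows %s",
                      df$subject_id[i[1]], paste(row_no[i], collapse = ", ")),
              "ap_conflict_error")
    }
    rec <- tryCatch(
      audiogram_record(df$subject_id[i[1]], age[i[1]], df$ear[i[1]],
                       stats::setNames(thr[i], frq[i]),
                       grp, df$source[i[1]]),
      ap_validation_error = function(e) {
        ap_warn(sprintf("rows %s rejected: %s",
                        paste(row_no[i], collapse = ", "),
                        conditionMessage(e)),
                "ap_rejected_record_warning")
        NULL
      })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }

  drop_monaural_when_binaural(records)
}

# Binaural records take precedence: reject per-ear records of any subject
# that also supplies a binaural record (spec invariant: never both).
drop_monaural_when_binaural <- function(records) {
  subj <- vapply(records, `[[`, character(1), "subject_id")
  ear <- vapply(records, `[[`, character(1), "ear")
  bin_subj <- unique(subj[ear == "binaural"])
  clash <- ear != "binaural" & subj %in% bin_subj
  if (any(clash)) {
    ap_warn(sprintf(
      "dropping %d per-ear record(s) for subject(s) %s that also have a binaural record",
      sum(clash), paste(unique(subj[clash]), collapse = ", ")),
      "ap_binaural_precedence_warning")
    records <- records[!clash]
  }
  records
}

#' Write an audiogram table
#'
#' Serializes records to the long CSV schema read by
#' [read_audiogram_table()]; a write/read round trip reproduces the record
#' list field for field.
#'
#' @param records List of `audiogram_record` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_audiogram_table <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(subject_id = r$subject_id,
               age_years = r$age,
               ear = r$ear,
               freq_hz = as.integer(names(r$thresholds)),
               threshold_db = unname(r$thresholds),
               group = r$group,
               source = r$source,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(subject_id = character(), age_years = numeric(),
                     ear = character(), freq_hz = integer(),
                     threshold_db = numeric(), group = character(),
                     source = character())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Collapse per-ear records to binaural records
#'
#' Pairs left/right records of each (subject, age) and replaces them with
#' their [binaural_average()]. Unpaired single-ear records are carried
#' through unchanged with a warning; binaural records pass through as is.
#'
#' @param records List of `audiogram_record` objects.
#' @return List of binaural (or unpaired single-ear) records.
#' @export
collapse_binaural <- function(records) {
  ear <- vapply(records, `[[`, character(1), "ear")
  out <- records[ear == "binaural"]
  mono <- records[ear != "binaural"]
  if (length(mono)) {
    key <- vapply(mono, function(r) paste(r$subject_id, r$age, sep = "\r"),
                  character(1))
    for (k in unique(key)) {
      grp <- mono[key == k]
      ears <- vapply(grp, `[[`, character(1), "ear")
      if (all(c("left", "right") %in% ears)) {
        out[[length(out) + 1L]] <-
          binaural_average(grp[[which(ears == "left")[1]]],
                           grp[[which(ears == "right")[1]]])
      } else {
        ap_warn(sprintf("subject '%s': only the %s ear available; used as is",
                        grp[[1]]$subject_id, ears[1]),
                "ap_single_ear_warning")
        out[[length(out) + 1L]] <- grp[[1]]
      }
    }
  }
  out
}
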