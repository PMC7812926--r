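#' Write / read a two-site recording as delimited text
#'
#' Plain-text interchange format: a header line then comma-separated
#' `time_s, brachial, ulnar` rows.
#'
#' @param recording a `ppg_recording` (or list with `time`, `brachial`,
#'   `ulnar`, `fs`).
#' @param path output file path.
#' @export
write_recording <- function(recording, path) {
  df <- data.frame(time_s = recording$time,
                   brachial = recording$brachial,
                   ulnar = recording$ulnar)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param path file written by [write_recording()].
#' @return a `ppg_recording` list (fs inferred from the time column).
#' @export
read_recording <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "brachial", "ulnar")
  if (!all(need %in% names(df))) {
    stop("malformed recording file ", path, ": expected columns ",
         paste(need, collapse = ", "))
  }
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(time = df$time_s, brachial = df$brachial, ulnar = df$ulnar,
                 fs = round(fs), sites = c("brachial", "ulnar")),
            class = "ppg_recording")
}

#' Write / read a cohort feature table as CSV
#'
#' Canonical column layout: `subject_id, gender, abp, lf_hf, rmssd, sa`.
#' `read_cohort()` accepts a `column_map` (named character vector
#' `canonical = file_column`) so externally produced tables can be ingested
#' after a documented renaming.
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @export
write_cohort <- function(table, path) {
  cols <- intersect(c("subject_id", "gender", "abp", "lf_hf", "rmssd", "sa",
                      "heart_rate", "td", "valid", "reason"), names(table))
  utils::write.csv(as.data.frame(table)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(sa = "STAI_Y_state")`.
#' @return a `cohort_table` data.frame.
#' @export
read_cohort <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) stop("column_map refers to missing column: ", src)
      names(df)[names(df) == src] <- canon
    }
  }
  need <- c("subject_id", "gender", "abp", "lf_hf", "rmssd", "sa")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("malformed cohort CSV ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  }
  if (!"valid" %in% names(df)) df$valid <- TRUE
  if (!"reason" %in% names(df)) df$reason <- NA_character_
  class(df) <- c("cohort_table", class(df))
  df
}

#' Serialize an analysis report to JSON
#'
#' Reports embed the configuration, seeds and input checksums used, so reruns
#' with the same inputs are byte-reproducible (no timestamps are written).
#'
#' @param report named list.
#' @param path output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# md5 of a file, for provenance fields
input_checksum <- function(path) unname(tools::md5sum(path))
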