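# CSV dialect throughout: comma-separated, header row, UTF-8.
# Timestamps are ISO-8601 on the local study clock ("YYYY-MM-DD HH:MM:SS");
# no timezone arithmetic is performed.

parse_timestamp <- function(x, what = "timestamp") {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = ACTI_TZ)
  for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- is.na(out)
    if (!any(idx)) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = ACTI_TZ))
  }
  if (any(is.na(out) & !is.na(x) & nzchar(x))) {
    bad <- which(is.na(out) & !is.na(x) & nzchar(x))[1]
    stop(sprintf("unparseable %s at row %d: '%s'", what, bad, x[bad]),
         call. = FALSE)
  }
  out
}

parse_date <- function(x, what = "date") {
  out <- as.Date(x, format = "%Y-%m-%d")
  if (any(is.na(out) & !is.na(x) & nzchar(x))) {
    bad <- which(is.na(out) & !is.na(x) & nzchar(x))[1]
    stop(sprintf("unparseable %s at row %d: '%s'", what, bad, x[bad]),
         call. = FALSE)
  }
  out
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required columns: %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

check_int_range <- function(x, lo, hi, what, file) {
  v <- suppressWarnings(as.integer(x))
  bad <- which(is.na(v) | v < lo | v > hi)
  if (length(bad) > 0) {
    stop(sprintf("%s: %s out of range [%d, %d] at row %d (value '%s')",
                 file, what, lo, hi, bad[1], x[bad[1]]), call. = FALSE)
  }
  v
}

#' Read an epoch-count CSV into an epoch series
#'
#' Expects columns `timestamp` and `counts` (column names remappable via
#' `schema`).  Records are sorted by time, uniform spacing is enforced
#' and the epoch length is inferred from the modal inter-record gap.
#'
#' @param path CSV file path.
#' @param schema Named list mapping the logical names `timestamp` and
#'   `counts` to the file's column names.
#' @param participant_id Identifier attached to the resulting series.
#' @return An [epoch_series()].
#' @export
read_epoch_csv <- function(path,
                           schema = list(timestamp = "timestamp",
                                         counts = "counts"),
                           participant_id = NA_character_) {
  df <- read_csv_checked(path, unlist(schema))
  ts <- parse_timestamp(df[[schema$timestamp]])
  counts <- suppressWarnings(as.numeric(df[[schema$counts]]))
  if (any(is.na(counts))) {
    stop(sprintf("%s: non-numeric counts at row %d", basename(path),
                 which(is.na(counts))[1]), call. = FALSE)
  }
  if (any(counts < 0)) {
    stop(sprintf("%s: negative counts at row %d", basename(path),
                 which(counts < 0)[1]), call. = FALSE)
  }
  ord <- order(ts)
  epoch_series(ts[ord], counts[ord], participant_id = participant_id,
               require_uniform = TRUE)
}

#' Read a wear-log CSV
#'
#' Columns: `participant_id`, `start`, `end`, `source`
#' (`participant_log` or `algorithm`).  Every interval must have
#' `start < end`.
#'
#' @param path CSV file path.
#' @return Data frame of wear-log entries, sorted by participant then
#'   start time.
#' @export
read_wearlog_csv <- function(path) {
  df <- read_csv_checked(path, c("participant_id", "start", "end", "source"))
  out <- data.frame(participant_id = df$participant_id,
                    start = parse_timestamp(df$start, "start"),
                    end = parse_timestamp(df$end, "end"),
                    source = df$source, stringsAsFactors = FALSE)
  if (nrow(out) > 0) {
    bad <- which(!(out$start < out$end))
    if (length(bad) > 0) {
      stop(sprintf("%s: wear-log start >= end at row %d", basename(path),
                   bad[1]), call. = FALSE)
    }
    bad_src <- which(!out$source %in% c("participant_log", "algorithm"))
    if (length(bad_src) > 0) {
      stop(sprintf("%s: unknown wear-log source '%s' at row %d",
                   basename(path), out$source[bad_src[1]], bad_src[1]),
           call. = FALSE)
    }
    out <- out[order(out$participant_id, out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a 48-hour survey CSV
#'
#' Columns: `participant_id`, `date`, `pcss_total`, `pcss_form`
#' (`likert` or `dichotomous`), `rta_stage` (1--6), `rts_stage` (1--5),
#' `cognitive_level` (1--5), and optionally `symptom_free`
#' (true/false answer to the two-week symptom screening question).
#' The symptom-score range is validated against the form: 0--132 for the
#' 22-item 0--6 Likert checklist, 0--22 for the dichotomous child form.
#' Records are sorted by date within participant; duplicate dates keep
#' the last record (resubmission semantics).
#'
#' @param path CSV file path.
#' @return Data frame of survey records.
#' @export
read_survey_csv <- function(path) {
  req <- c("participant_id", "date", "pcss_total", "pcss_form",
           "rta_stage", "rts_stage", "cognitive_level")
  df <- read_csv_checked(path, req)
  n <- nrow(df)
  bad_form <- which(!df$pcss_form %in% c("likert", "dichotomous"))
  if (length(bad_form) > 0) {
    stop(sprintf("%s: unknown pcss_form '%s' at row %d", basename(path),
                 df$pcss_form[bad_form[1]], bad_form[1]), call. = FALSE)
  }
  pcss <- integer(n)
  if (n > 0) {
    lik <- df$pcss_form == "likert"
    if (any(lik)) {
      pcss[lik] <- check_int_range(df$pcss_total[lik], 0, 132,
                                   "pcss_total (likert)", basename(path))
    }
    if (any(!lik)) {
      pcss[!lik] <- check_int_range(df$pcss_total[!lik], 0, 22,
                                    "pcss_total (dichotomous)", basename(path))
    }
  }
  out <- data.frame(
    participant_id = df$participant_id,
    date = parse_date(df$date),
    pcss_total = pcss,
    pcss_form = df$pcss_form,
    rta_stage = check_int_range(df$rta_stage, 1, 6, "rta_stage", basename(path)),
    rts_stage = check_int_range(df$rts_stage, 1, 5, "rts_stage", basename(path)),
    cognitive_level = check_int_range(df$cognitive_level, 1, 5,
                                      "cognitive_level", basename(path)),
    stringsAsFactors = FALSE)
  out$symptom_free <- if ("symptom_free" %in% names(df)) {
    tolower(df$symptom_free) %in% c("true", "t", "1", "yes")
  } else FALSE
  if (n > 0) {
    # stable sort; last record per (participant, date) wins
    out <- out[order(out$participant_id, out$date), , drop = FALSE]
    keep <- !duplicated(out[, c("participant_id", "date")], fromLast = TRUE)
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Read a cohort roster CSV
#'
#' Columns: `participant_id`, `injury_datetime`, `resolution_date`
#' (empty when symptoms never resolved in the study window), `reinjured`,
#' `withdrew`.  A resolution date before the injury is an error.
#'
#' @param path CSV file path.
#' @return Data frame of roster entries.
#' @export
read_roster_csv <- function(path) {
  req <- c("participant_id", "injury_datetime", "resolution_date",
           "reinjured", "withdrew")
  df <- read_csv_checked(path, req)
  res <- rep(as.Date(NA), nrow(df))
  has <- !is.na(df$resolution_date) & nzchar(df$resolution_date)
  res[has] <- parse_date(df$resolution_date[has], "resolution_date")
  out <- data.frame(
    participant_id = df$participant_id,
    injury_datetime = parse_timestamp(df$injury_datetime, "injury_datetime"),
    resolution_date = res,
    reinjured = tolower(df$reinjured) %in% c("true", "t", "1", "yes"),
    withdrew = tolower(df$withdrew) %in% c("true", "t", "1", "yes"),
    stringsAsFactors = FALSE)
  bad <- which(!is.na(out$resolution_date) &
                 out$resolution_date <
                   as.Date(format(out$injury_datetime, "%Y-%m-%d", tz = ACTI_TZ)))
  if (length(bad) > 0) {
    stop(sprintf("%s: resolution_date before injury at row %d",
                 basename(path), bad[1]), call. = FALSE)
  }
  out
}

fmt_ts <- function(x) format(x, "%Y-%m-%d %H:%M:%S", tz = ACTI_TZ)

#' Write an epoch series back to CSV
#' @param series An [epoch_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path) {
  stopifnot(inherits(series, "epoch_series"))
  utils::write.csv(data.frame(timestamp = fmt_ts(series$timestamps),
                              counts = series$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a wear log to CSV
#' @param log Wear-log data frame (`participant_id`, `start`, `end`, `source`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wearlog_csv <- function(log, path) {
  out <- data.frame(participant_id = log$participant_id,
                    start = fmt_ts(log$start), end = fmt_ts(log$end),
                    source = log$source)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write survey records to CSV
#' @param surveys Survey data frame as from [read_survey_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(surveys, path) {
  out <- surveys
  out$date <- format(out$date, "%Y-%m-%d")
  out$symptom_free <- tolower(as.character(out$symptom_free))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort roster to CSV
#' @param roster Roster data frame as from [read_roster_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roster_csv <- function(roster, path) {
  out <- data.frame(
    participant_id = roster$participant_id,
    injury_datetime = fmt_ts(roster$injury_datetime),
    resolution_date = ifelse(is.na(roster$resolution_date), "",
                             format(roster$resolution_date, "%Y-%m-%d")),
    reinjured = tolower(as.character(roster$reinjured)),
    withdrew = tolower(as.character(roster$withdrew)))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
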