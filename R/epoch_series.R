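# Timestamps are handled on the local study clock with no timezone
# arithmetic; internally everything is POSIXct in UTC so that arithmetic
# is DST-free.
ACTI_TZ <- "UTC"

VALID_EPOCH_LENGTHS <- c(1, 5, 10, 15, 30, 60)

#' Construct an epoch series
#'
#' An `epoch_series` holds one participant's uniformly gridded activity
#' counts: strictly increasing timestamps whose gaps are all multiples of
#' `epoch_length` (a freshly read file has no gaps; gaps appear after
#' wear masking).
#'
#' @param timestamps POSIXct vector, strictly increasing.
#' @param counts Non-negative integer vector, one per timestamp.
#' @param epoch_length Epoch length in seconds; inferred from the modal
#'   gap when `NULL`.
#' @param participant_id Optional participant identifier.
#' @param require_uniform If `TRUE`, any gap other than `epoch_length`
#'   itself is an error (the contract for raw files).
#' @return An `epoch_series` object.
#' @export
epoch_series <- function(timestamps, counts, epoch_length = NULL,
                         participant_id = NA_character_,
                         require_uniform = FALSE) {
  stopifnot(inherits(timestamps, "POSIXct"))
  if (length(timestamps) != length(counts)) {
    stop("timestamps and counts differ in length", call. = FALSE)
  }
  counts <- as.integer(counts)
  if (any(is.na(counts))) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)

  gaps <- as.numeric(diff(timestamps), units = "secs")
  # POSIXct arithmetic is double-based; snap to whole seconds before
  # divisibility checks
  snapped <- round(gaps)
  gaps <- ifelse(abs(gaps - snapped) < 1e-6, snapped, gaps)
  if (any(gaps <= 0)) stop("timestamps not strictly increasing", call. = FALSE)
  if (is.null(epoch_length)) {
    if (length(gaps) == 0) stop("cannot infer epoch length from one epoch",
                                call. = FALSE)
    cand <- gaps[gaps %in% VALID_EPOCH_LENGTHS]
    if (length(cand) == 0) {
      stop(sprintf(
        "non-uniform epoch spacing: no standard epoch length fits (first gap %gs after %s)",
        gaps[1], format(timestamps[1], "%Y-%m-%d %H:%M:%S", tz = ACTI_TZ)),
        call. = FALSE)
    }
    tab <- table(cand)
    epoch_length <- as.numeric(names(tab)[which.max(tab)])
  }
  if (!epoch_length %in% VALID_EPOCH_LENGTHS) {
    stop("unsupported epoch length: ", epoch_length, call. = FALSE)
  }
  if (length(gaps) > 0) {
    off <- gaps %% epoch_length != 0
    if (require_uniform) off <- off | (gaps != epoch_length)
    if (any(off)) {
      i <- which(off)[1]
      stop(sprintf(
        "non-uniform epoch spacing: gap of %gs after %s (expected %gs)",
        gaps[i], format(timestamps[i], "%Y-%m-%d %H:%M:%S", tz = ACTI_TZ),
        epoch_length), call. = FALSE)
    }
  }
  structure(
    list(participant_id = participant_id,
         timestamps = timestamps,
         counts = counts,
         epoch_length = epoch_length),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("Epoch series%s: %d epochs of %gs",
              if (is.na(x$participant_id)) ""
              else paste0(" [", x$participant_id, "]"),
              length(x$counts), x$epoch_length))
  if (length(x$counts) > 0) {
    cat(sprintf(", %s to %s",
                format(min(x$timestamps), "%Y-%m-%d %H:%M", tz = ACTI_TZ),
                format(max(x$timestamps), "%Y-%m-%d %H:%M", tz = ACTI_TZ)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$counts)

#' Re-aggregate an epoch series to a coarser epoch length
#'
#' Sums counts within non-overlapping windows aligned to the series
#' start.  The target must be an integer multiple of the source epoch
#' length; a trailing partial window is dropped.
#'
#' @param series An [epoch_series()].
#' @param target_length Target epoch length in seconds.
#' @return A new `epoch_series` at `target_length`.
#' @export
#' @examples
#' ts <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC") + seq(0, 50, by = 10)
#' s <- epoch_series(ts, c(10, 20, 30, 1, 2, 3), epoch_length = 10)
#' reaggregate_epochs(s, 30)$counts  # 60, 6
reaggregate_epochs <- function(series, target_length) {
  stopifnot(inherits(series, "epoch_series"))
  src <- series$epoch_length
  if (target_length %% src != 0) {
    stop(sprintf("target length %gs is not a multiple of source %gs",
                 target_length, src), call. = FALSE)
  }
  k <- target_length / src
  if (k == 1) return(series)
  n_out <- floor(length(series$counts) / k)
  if (n_out == 0) {
    return(epoch_series(series$timestamps[0], integer(0),
                        epoch_length = target_length,
                        participant_id = series$participant_id))
  }
  idx <- seq_len(n_out * k)
  grp <- rep(seq_len(n_out), each = k)
  counts <- as.integer(tapply(series$counts[idx], grp, sum))
  ts <- series$timestamps[seq(1, by = k, length.out = n_out)]
  epoch_series(ts, counts, epoch_length = target_length,
               participant_id = series$participant_id)
}

#' Detect non-wear as long runs of zero counts
#'
#' Flags every maximal run of consecutive zero-count epochs lasting at
#' least `zero_run_minutes` as a non-wear interval.  This reproducible
#' zero-run rule stands in for manual log reconciliation and visual
#' inspection of wear traces.
#'
#' @param series An [epoch_series()].
#' @param zero_run_minutes Minimal run duration in minutes (default 60).
#' @return Wear-log data frame with columns `start`, `end` (POSIXct,
#'   half-open interval) and `source = "algorithm"`; zero rows when no
#'   run qualifies.
#' @export
detect_nonwear <- function(series, zero_run_minutes = 60) {
  stopifnot(inherits(series, "epoch_series"))
  if (length(series$counts) == 0) stop("empty epoch series", call. = FALSE)
  r <- rle(series$counts == 0)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  need <- ceiling(zero_run_minutes * 60 / series$epoch_length)
  keep <- r$values & r$lengths >= need
  # runs must also be contiguous in time (no masked holes inside)
  out <- lapply(which(keep), function(i) {
    span <- as.numeric(series$timestamps[ends[i]] - series$timestamps[starts[i]],
                       units = "secs")
    if (abs(span - (ends[i] - starts[i]) * series$epoch_length) > 1e-6) {
      return(NULL)
    }
    data.frame(start = series$timestamps[starts[i]],
               end = series$timestamps[ends[i]] + series$epoch_length,
               source = "algorithm", stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(start = series$timestamps[0], end = series$timestamps[0],
                      source = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Remove epochs covered by non-wear intervals
#'
#' Drops every epoch whose half-open interval overlaps any wear-log
#' entry.  Participant-logged and algorithm-detected intervals are
#' treated identically (union semantics: overlapping entries never
#' remove an epoch twice).
#'
#' @param series An [epoch_series()].
#' @param log Wear-log data frame with `start` and `end` POSIXct columns;
#'   may have zero rows.
#' @return The masked `epoch_series` (gaps allowed).
#' @export
apply_wear_mask <- function(series, log) {
  stopifnot(inherits(series, "epoch_series"))
  if (is.null(log) || nrow(log) == 0) return(series)
  if (any(log$end <= log$start)) stop("wear-log entry with end <= start",
                                      call. = FALSE)
  t0 <- as.numeric(series$timestamps)
  t1 <- t0 + series$epoch_length
  drop <- rep(FALSE, length(t0))
  for (i in seq_len(nrow(log))) {
    drop <- drop | (t0 < as.numeric(log$end[i]) & t1 > as.numeric(log$start[i]))
  }
  epoch_series(series$timestamps[!drop], series$counts[!drop],
               epoch_length = series$epoch_length,
               participant_id = series$participant_id)
}

#' Summarise a wear-masked epoch series into daily summaries
#'
#' Splits the series at calendar midnight (local clock), classifies every
#' worn epoch with the supplied cut points and accumulates wear and
#' per-intensity minutes.  A day is valid when its wear time lies within
#' the inclusive `[valid_min, valid_max]` bounds (defaults 6 h and 19 h).
#'
#' @param series Wear-masked [epoch_series()].
#' @param thresholds [intensity_thresholds()] matching the epoch length.
#' @param valid_min,valid_max Inclusive wear-minute bounds for a valid day.
#' @return A `daily_summary` data frame with one row per calendar day:
#'   `date`, `wear_minutes`, `sedentary_minutes`, `light_minutes`,
#'   `moderate_minutes`, `vigorous_minutes`, `mvpa_minutes`, `valid`,
#'   plus a list column `epoch_classes` holding the day's ordered
#'   intensity labels.
#' @export
summarize_days <- function(series, thresholds, valid_min = 360,
                           valid_max = 1140) {
  stopifnot(inherits(series, "epoch_series"),
            inherits(thresholds, "intensity_thresholds"))
  if (thresholds$epoch_length != series$epoch_length) {
    stop("threshold epoch length does not match series", call. = FALSE)
  }
  min_per_epoch <- series$epoch_length / 60
  if (length(series$counts) == 0) {
    out <- data.frame(date = as.Date(character(0)),
                      wear_minutes = numeric(0), sedentary_minutes = numeric(0),
                      light_minutes = numeric(0), moderate_minutes = numeric(0),
                      vigorous_minutes = numeric(0), mvpa_minutes = numeric(0),
                      valid = logical(0))
    out$epoch_classes <- list()
    class(out) <- c("daily_summary", "data.frame")
    return(out)
  }
  classes <- classify_epoch(series$counts, thresholds)
  dates <- as.Date(format(series$timestamps, "%Y-%m-%d", tz = ACTI_TZ))
  split_idx <- split(seq_along(classes), dates)
  rows <- lapply(names(split_idx), function(d) {
    cl <- classes[split_idx[[d]]]
    n_by <- vapply(INTENSITY_LEVELS, function(lv) sum(cl == lv), numeric(1))
    mins <- n_by * min_per_epoch
    wear <- length(cl) * min_per_epoch
    data.frame(date = as.Date(d),
               wear_minutes = wear,
               sedentary_minutes = mins[["sedentary"]],
               light_minutes = mins[["light"]],
               moderate_minutes = mins[["moderate"]],
               vigorous_minutes = mins[["vigorous"]],
               mvpa_minutes = mins[["moderate"]] + mins[["vigorous"]],
               valid = wear >= valid_min && wear <= valid_max,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$epoch_classes <- lapply(names(split_idx), function(d) classes[split_idx[[d]]])
  attr(out, "epoch_length") <- series$epoch_length
  class(out) <- c("daily_summary", "data.frame")
  out
}
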