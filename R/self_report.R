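#' Derive a subjective adherence label from the 48-hour surveys
#'
#' The study's subjective criterion — "has the child been following the
#' guidelines correctly?" — rests on self-reported progression through
#' the protocol stages together with a decreasing symptom score.  This
#' is operationalised as an auditable proxy: the reported stage sequence
#' must never regress, and the symptom score must end at or below its
#' starting value (`pcss_rule = "endpoint"`, the default, tolerant of
#' the fluctuation typical at a 48-hour cadence) or never increase
#' (`pcss_rule = "monotone"`).  The original label was a judgement call
#' by research personnel; this proxy makes the criterion explicit and
#' reproducible.
#'
#' @param surveys Survey data frame for one participant (any order;
#'   sorted internally by date).
#' @param protocol `"rta"` or `"rts"` — which stage column to examine.
#' @param pcss_rule `"endpoint"` or `"monotone"`.
#' @return `"Adhered"`, `"Did not adhere"`, or `"Insufficient data"`
#'   (fewer than 2 surveys).
#' @export
#' @examples
#' s <- data.frame(date = as.Date("2024-01-01") + c(0, 2, 4),
#'                 rta_stage = c(1, 2, 3), rts_stage = c(1, 1, 2),
#'                 pcss_total = c(30, 20, 5))
#' label_self_report(s, "rta")
label_self_report <- function(surveys, protocol = c("rta", "rts"),
                              pcss_rule = c("endpoint", "monotone")) {
  protocol <- match.arg(protocol)
  pcss_rule <- match.arg(pcss_rule)
  if (is.null(surveys) || nrow(surveys) < 2) return("Insufficient data")
  surveys <- surveys[order(surveys$date), , drop = FALSE]
  stages <- surveys[[paste0(protocol, "_stage")]]
  pcss <- surveys$pcss_total
  stage_ok <- all(diff(stages) >= 0)
  pcss_ok <- if (pcss_rule == "endpoint") {
    pcss[length(pcss)] <= pcss[1]
  } else {
    all(diff(pcss) <= 0)
  }
  if (stage_ok && pcss_ok) "Adhered" else "Did not adhere"
}

#' Combine protocol-specific labels into the overall label
#'
#' A participant adhered overall only when adherent to both the
#' Return-to-Activity and Return-to-School protocols; adhering to one
#' but not both is deemed "Did not adhere".  `"Insufficient data"` in
#' either input propagates.
#'
#' @param rta,rts Labels from [label_self_report()].
#' @return Combined label.
#' @export
combine_labels <- function(rta, rts) {
  labs <- c("Adhered", "Did not adhere", "Insufficient data")
  stopifnot(rta %in% labs, rts %in% labs)
  if (rta == "Insufficient data" || rts == "Insufficient data") {
    return("Insufficient data")
  }
  if (rta == "Adhered" && rts == "Adhered") "Adhered" else "Did not adhere"
}

#' Whole days from injury to symptom resolution
#'
#' Floor of the elapsed time between the injury date-time and the
#' resolution date; `NA` (censored) when symptoms never resolved within
#' the study window.
#'
#' @param injury_datetime POSIXct injury time.
#' @param resolution_date Date of verified symptom resolution, or `NA`.
#' @return Integer days, or `NA` when censored.
#' @export
#' @examples
#' time_to_resolution(as.POSIXct("2024-01-01 10:00:00", tz = "UTC"),
#'                    as.Date("2024-01-14"))  # 13
time_to_resolution <- function(injury_datetime, resolution_date) {
  if (is.na(resolution_date)) return(NA_integer_)
  injury_date <- as.Date(format(injury_datetime, "%Y-%m-%d", tz = ACTI_TZ))
  days <- as.integer(resolution_date - injury_date)
  if (days < 0) stop("resolution date precedes injury", call. = FALSE)
  days
}

#' Zero-impute the symptom score for symptom-free respondents
#'
#' Participants answering "no" to having had any concussion symptoms in
#' the last two weeks are assigned a symptom score of 0, overriding
#' whatever total the checklist produced.
#'
#' @param survey One survey record (list or one-row data frame).
#' @param symptom_free_flag Logical answer to the screening question;
#'   when omitted the record's own `symptom_free` column is used.
#' @return The record with `pcss_total` set to 0 when symptom-free.
#' @export
impute_pcss_zero <- function(survey, symptom_free_flag = NULL) {
  flag <- if (is.null(symptom_free_flag)) {
    isTRUE(survey$symptom_free) || isTRUE(survey$symptom_free[1])
  } else {
    isTRUE(symptom_free_flag)
  }
  if (flag) survey$pcss_total <- 0L
  survey
}

#' Apply symptom-free zero-imputation across a survey table
#'
#' @param surveys Survey data frame with a logical `symptom_free` column.
#' @return The data frame with `pcss_total` zeroed where symptom-free.
#' @export
impute_pcss_zero_all <- function(surveys) {
  if (!is.null(surveys$symptom_free)) {
    surveys$pcss_total[surveys$symptom_free] <- 0L
  }
  surveys
}

#' Recovery outcomes for one participant
#'
#' Collects the recovery-time quantities used by the group comparisons:
#' whole days from injury to symptom resolution (censored when absent),
#' the symptom score at resolution (the score of the latest survey on or
#' before the resolution date, after zero-imputation), and the first day
#' each protocol stage was reported.
#'
#' @param roster_row One row of the roster.
#' @param surveys Survey data frame for the participant.
#' @param horizon_days Censoring horizon in days after injury.
#' @return List `participant_id`, `days_to_resolution`, `censored`,
#'   `pcss_at_resolution`, `days_to_stage` (named vector over RTA stages
#'   reported).
#' @export
recovery_outcome <- function(roster_row, surveys, horizon_days = 180) {
  days <- time_to_resolution(roster_row$injury_datetime,
                             roster_row$resolution_date)
  censored <- is.na(days)
  if (!censored && days > horizon_days) {
    days <- NA_integer_
    censored <- TRUE
  }
  injury_date <- as.Date(format(roster_row$injury_datetime, "%Y-%m-%d",
                                tz = ACTI_TZ))
  pcss_res <- NA_integer_
  days_to_stage <- stats::setNames(rep(NA_integer_, 6), paste0("stage", 1:6))
  if (!is.null(surveys) && nrow(surveys) > 0) {
    surveys <- impute_pcss_zero_all(surveys[order(surveys$date), ,
                                            drop = FALSE])
    if (!censored) {
      at <- which(surveys$date <= roster_row$resolution_date)
      if (length(at) > 0) pcss_res <- surveys$pcss_total[max(at)]
    }
    for (s in 1:6) {
      hit <- which(surveys$rta_stage >= s)
      if (length(hit) > 0) {
        days_to_stage[[paste0("stage", s)]] <-
          as.integer(surveys$date[min(hit)] - injury_date)
      }
    }
  }
  list(participant_id = roster_row$participant_id,
       days_to_resolution = days, censored = censored,
       pcss_at_resolution = pcss_res, days_to_stage = days_to_stage)
}
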