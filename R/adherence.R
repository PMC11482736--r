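MVPA_SET <- c("moderate", "vigorous")
NONSED_SET <- c("light", "moderate", "vigorous")

#' Machine-readable rule for one RTA stage
#'
#' Objective activity rules exist for stages 1--3 of the staged
#' Return-to-Activity protocol; these are the only stages with
#' quantifiable activity amounts:
#' \itemize{
#'   \item Stage 1: unlimited light activity, moderate-to-vigorous
#'     activity (MVPA) capped at 2.5\% of wear time, and no consecutive
#'     bout of 5 minutes or more at any non-sedentary intensity.
#'   \item Stage 2: baseline activity observed in stage 1, plus an extra
#'     30 minutes of light activity, with no MVPA bout of 5 minutes or
#'     more.
#'   \item Stage 3: baseline activity observed in stage 2, plus an extra
#'     60 minutes of MVPA, in at most two bouts of at most 15 minutes.
#' }
#'
#' @param stage Integer stage number, 1--3.  Stages 4--6 have no
#'   objective rule and raise an error.
#' @return A `stage_rule` list with fields `stage`,
#'   `mvpa_wear_fraction_cap`, `extra_lpa_minutes`, `extra_mvpa_minutes`,
#'   `forbidden_bout` (list: `intensity_set`, `min_duration`) and
#'   `allowed_mvpa_bouts` (list: `max_count`, `max_duration`), unused
#'   fields `NULL`.
#' @export
stage_rule <- function(stage) {
  stage <- as.integer(stage)
  if (length(stage) != 1 || is.na(stage) || stage < 1 || stage > 6) {
    stop("stage must be a single integer in 1..6", call. = FALSE)
  }
  if (stage > 3) {
    stop(sprintf(paste0("no objective rule for RTA stage %d: only stages ",
                        "1-3 have quantifiable activity amounts"), stage),
         call. = FALSE)
  }
  base <- list(stage = stage, mvpa_wear_fraction_cap = NULL,
               extra_lpa_minutes = NULL, extra_mvpa_minutes = NULL,
               forbidden_bout = NULL, allowed_mvpa_bouts = NULL)
  rule <- switch(stage,
    `1` = utils::modifyList(base, list(
      mvpa_wear_fraction_cap = 0.025,
      forbidden_bout = list(intensity_set = NONSED_SET, min_duration = 5))),
    `2` = utils::modifyList(base, list(
      extra_lpa_minutes = 30,
      forbidden_bout = list(intensity_set = MVPA_SET, min_duration = 5))),
    `3` = utils::modifyList(base, list(
      extra_mvpa_minutes = 60,
      allowed_mvpa_bouts = list(max_count = 2, max_duration = 15,
                                min_duration = 5))))
  structure(rule, class = "stage_rule")
}

#' Default rules for RTA stages 1--3
#' @return Named list `stage1`..`stage3` of [stage_rule()] objects.
#' @export
default_stage_rules <- function() {
  stats::setNames(lapply(1:3, stage_rule), paste0("stage", 1:3))
}

#' Find activity bouts in a day's epoch classes
#'
#' A bout is a maximal run of consecutive epochs whose intensity class
#' belongs to `intensity_set`, lasting at least `min_duration` minutes.
#' By default a single epoch outside the set breaks the run
#' (`tolerance_epochs = 0`); a positive tolerance merges runs separated
#' by at most that many off-class epochs.
#'
#' @param epoch_classes Character vector of intensity labels for one
#'   day's worn epochs, in time order.
#' @param intensity_set Subset of
#'   `c("sedentary", "light", "moderate", "vigorous")`.
#' @param min_duration Minimal bout duration in minutes.
#' @param epoch_length Epoch length in seconds (default 30).
#' @param tolerance_epochs Number of off-class epochs tolerated inside a
#'   bout before it breaks (default 0).
#' @return Data frame with one row per bout: `start_index`, `n_epochs`,
#'   `duration` (minutes, counting only in-set epochs).
#' @export
#' @examples
#' cl <- c(rep("sedentary", 5), rep("moderate", 12), "sedentary")
#' find_bouts(cl, c("moderate", "vigorous"), min_duration = 5)
find_bouts <- function(epoch_classes, intensity_set, min_duration = 5,
                       epoch_length = 30, tolerance_epochs = 0) {
  stopifnot(all(intensity_set %in% INTENSITY_LEVELS))
  empty <- data.frame(start_index = integer(0), n_epochs = integer(0),
                      duration = numeric(0))
  if (length(epoch_classes) == 0) return(empty)
  inset <- epoch_classes %in% intensity_set
  if (!any(inset)) return(empty)
  r <- rle(inset)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values],
                     n = r$lengths[r$values])
  if (tolerance_epochs > 0 && nrow(runs) > 1) {
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1
      if (gap <= tolerance_epochs) {
        merged$end[nrow(merged)] <- runs$end[i]
        merged$n[nrow(merged)] <- merged$n[nrow(merged)] + runs$n[i]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
    runs <- merged
  }
  dur <- runs$n * epoch_length / 60
  keep <- dur >= min_duration
  if (!any(keep)) return(empty)
  data.frame(start_index = runs$start[keep],
             n_epochs = as.integer(runs$end[keep] - runs$start[keep] + 1),
             duration = dur[keep])
}

#' Baseline daily activity from a prior stage
#'
#' The stage-2 and stage-3 rules permit "baseline activity observed" in
#' the previous stage; this is operationalised as the arithmetic mean of
#' daily light and MVPA minutes over that stage's valid days.  With no
#' valid prior-stage days the configured fallback is used and flagged.
#'
#' @param summaries `daily_summary` rows (valid days of the prior stage);
#'   may have zero rows.
#' @param fallback Named list/vector with `lpa` and `mvpa` minutes used
#'   when `summaries` is empty.
#' @param source_stage Stage the baseline was observed in (bookkeeping).
#' @return List with `lpa_minutes`, `mvpa_minutes`, `n_days`,
#'   `source_stage`, `fallback_used`.
#' @export
compute_baseline <- function(summaries,
                             fallback = default_config()$baseline$fallback,
                             source_stage = NA_integer_) {
  if (is.null(summaries) || nrow(summaries) == 0) {
    return(list(lpa_minutes = as.numeric(fallback$lpa),
                mvpa_minutes = as.numeric(fallback$mvpa),
                n_days = 0L, source_stage = source_stage,
                fallback_used = TRUE))
  }
  list(lpa_minutes = mean(summaries$light_minutes),
       mvpa_minutes = mean(summaries$mvpa_minutes),
       n_days = nrow(summaries), source_stage = source_stage,
       fallback_used = FALSE)
}

day_fields <- function(day) {
  # accepts a one-row daily_summary data frame or an equivalent list
  if (is.data.frame(day)) {
    stopifnot(nrow(day) == 1)
    list(valid = day$valid, wear = day$wear_minutes,
         lpa = day$light_minutes, mvpa = day$mvpa_minutes,
         classes = day$epoch_classes[[1]])
  } else {
    list(valid = day$valid, wear = day$wear_minutes,
         lpa = day$light_minutes, mvpa = day$mvpa_minutes,
         classes = day$epoch_classes)
  }
}

#' Evaluate the stage-1 rule on one valid day
#'
#' Adherent when MVPA minutes are at most 2.5\% of wear minutes
#' (inclusive) and no run of 5+ minutes occurs at any non-sedentary
#' intensity.  Violation codes: `"mvpa_cap"`, `"bout"`.
#'
#' @param day One row of a `daily_summary` (must be valid).
#' @param rule A stage-1 [stage_rule()].
#' @param epoch_length Epoch length in seconds.
#' @param tolerance_epochs Bout interruption tolerance.
#' @return List `(adherent, violations)`.
#' @export
stage1_day <- function(day, rule = stage_rule(1), epoch_length = 30,
                       tolerance_epochs = 0) {
  stopifnot(rule$stage == 1)
  d <- day_fields(day)
  if (!isTRUE(d$valid)) stop("stage rules apply to valid days only",
                             call. = FALSE)
  viol <- character(0)
  if (d$mvpa > rule$mvpa_wear_fraction_cap * d$wear) viol <- c(viol, "mvpa_cap")
  bouts <- find_bouts(d$classes, rule$forbidden_bout$intensity_set,
                      rule$forbidden_bout$min_duration, epoch_length,
                      tolerance_epochs)
  if (nrow(bouts) > 0) viol <- c(viol, "bout")
  list(adherent = length(viol) == 0, violations = viol)
}

#' Evaluate the stage-2 rule on one valid day
#'
#' Adherent when light minutes do not exceed the stage-1 baseline plus
#' 30, MVPA minutes do not exceed the stage-1 baseline MVPA, and no MVPA
#' bout lasts 5 minutes or more.  Violation codes: `"lpa_cap"`,
#' `"mvpa_cap"`, `"mvpa_bout"`.
#'
#' @inheritParams stage1_day
#' @param rule A stage-2 [stage_rule()].
#' @param baseline Stage-1 [compute_baseline()] result.
#' @param mvpa_cap_mode `"baseline"` (cap MVPA at the stage-1 baseline)
#'   or `"none"` (no total-MVPA clause).
#' @return List `(adherent, violations)`.
#' @export
stage2_day <- function(day, rule = stage_rule(2), baseline,
                       epoch_length = 30, tolerance_epochs = 0,
                       mvpa_cap_mode = "baseline") {
  stopifnot(rule$stage == 2)
  d <- day_fields(day)
  if (!isTRUE(d$valid)) stop("stage rules apply to valid days only",
                             call. = FALSE)
  viol <- character(0)
  if (d$lpa > baseline$lpa_minutes + rule$extra_lpa_minutes) {
    viol <- c(viol, "lpa_cap")
  }
  if (identical(mvpa_cap_mode, "baseline") &&
      d$mvpa > baseline$mvpa_minutes) {
    viol <- c(viol, "mvpa_cap")
  }
  bouts <- find_bouts(d$classes, rule$forbidden_bout$intensity_set,
                      rule$forbidden_bout$min_duration, epoch_length,
                      tolerance_epochs)
  if (nrow(bouts) > 0) viol <- c(viol, "mvpa_bout")
  list(adherent = length(viol) == 0, violations = viol)
}

#' Evaluate the stage-3 rule on one valid day
#'
#' Adherent when MVPA minutes do not exceed the stage-2 baseline plus
#' 60, at most two MVPA bouts of 5+ minutes occur, and every such bout
#' lasts at most 15 minutes (the bouts count toward, not on top of, the
#' extra 60 minutes).  Violation codes: `"mvpa_cap"`, `"bout_count"`,
#' `"bout_length"`.
#'
#' @inheritParams stage1_day
#' @param rule A stage-3 [stage_rule()].
#' @param baseline Stage-2 [compute_baseline()] result.
#' @return List `(adherent, violations)`.
#' @export
stage3_day <- function(day, rule = stage_rule(3), baseline,
                       epoch_length = 30, tolerance_epochs = 0) {
  stopifnot(rule$stage == 3)
  d <- day_fields(day)
  if (!isTRUE(d$valid)) stop("stage rules apply to valid days only",
                             call. = FALSE)
  viol <- character(0)
  if (d$mvpa > baseline$mvpa_minutes + rule$extra_mvpa_minutes) {
    viol <- c(viol, "mvpa_cap")
  }
  ab <- rule$allowed_mvpa_bouts
  bouts <- find_bouts(d$classes, MVPA_SET, ab$min_duration, epoch_length,
                      tolerance_epochs)
  if (nrow(bouts) > ab$max_count) viol <- c(viol, "bout_count")
  if (nrow(bouts) > 0 && any(bouts$duration > ab$max_duration)) {
    viol <- c(viol, "bout_length")
  }
  list(adherent = length(viol) == 0, violations = viol)
}

#' Evaluate any stage rule on one valid day
#'
#' Dispatcher over [stage1_day()], [stage2_day()] and [stage3_day()].
#'
#' @param stage Stage number 1--3.
#' @param day One row of a `daily_summary`.
#' @param baseline Prior-stage baseline (stages 2 and 3).
#' @param config Pipeline configuration (epoch length, bout tolerance,
#'   stage-2 MVPA cap mode).
#' @return List `(adherent, violations)`.
#' @export
evaluate_stage_day <- function(stage, day, baseline = NULL,
                               config = default_config()) {
  rule <- stage_rule(stage)
  el <- config$epoch_length_s
  tol <- config$bouts$tolerance_epochs
  switch(as.character(stage),
    "1" = stage1_day(day, rule, el, tol),
    "2" = stage2_day(day, rule, baseline, el, tol,
                     config$stage2$mvpa_cap_mode),
    "3" = stage3_day(day, rule, baseline, el, tol))
}

#' Assign a protocol stage to each day from the 48-hour surveys
#'
#' Each day takes the stage of the most recent survey on or before it
#' (carry-forward); days before the first survey take the first survey's
#' stage and are flagged `carried_back`.
#'
#' @param dates Date vector of days needing a stage.
#' @param surveys Survey data frame for one participant (sorted or not);
#'   must be non-empty.
#' @param stage_col Which stage column to use (default `"rta_stage"`).
#' @return Data frame `date`, `stage`, `carried_back`.
#' @export
assign_stage_days <- function(dates, surveys, stage_col = "rta_stage") {
  if (is.null(surveys) || nrow(surveys) == 0) {
    stop("no surveys: cannot assign stages to days", call. = FALSE)
  }
  surveys <- surveys[order(surveys$date), , drop = FALSE]
  idx <- findInterval(as.numeric(dates), as.numeric(surveys$date))
  carried <- idx == 0
  idx[carried] <- 1L
  data.frame(date = dates, stage = surveys[[stage_col]][idx],
             carried_back = carried)
}

#' Label a participant's adherence to one stage
#'
#' Under the `any_day` policy (the rule used for the headline adherence
#' counts) a participant adheres to a stage if at least one valid day
#' was adherent.  Under the `fraction` policy the adherent fraction of
#' valid days must reach `fraction_threshold` (inclusive; default 0.8,
#' the stricter a-priori criterion).  With no valid days the label is
#' `"Insufficient data"`.
#'
#' @param verdicts Logical vector of per-day adherence on valid days.
#' @param policy `"any_day"` or `"fraction"`.
#' @param fraction_threshold Inclusive threshold for the fraction policy.
#' @return List `n_valid_days`, `n_adherent_days`, `label`.
#' @export
#' @examples
#' label_participant_stage(c(FALSE, TRUE, FALSE))$label          # Adhered
#' label_participant_stage(rep(c(TRUE, FALSE), c(4, 1)),
#'                         policy = "fraction")$label            # Adhered
label_participant_stage <- function(verdicts,
                                    policy = c("any_day", "fraction"),
                                    fraction_threshold = 0.8) {
  policy <- match.arg(policy)
  n <- length(verdicts)
  k <- sum(verdicts)
  label <- if (n == 0) {
    "Insufficient data"
  } else if (policy == "any_day") {
    if (k >= 1) "Adhered" else "Did not adhere"
  } else {
    if (k / n >= fraction_threshold) "Adhered" else "Did not adhere"
  }
  list(n_valid_days = n, n_adherent_days = as.integer(k), label = label)
}

#' Score one participant's stage 1--3 adherence
#'
#' Runs the full objective-adherence chain for one participant: assigns
#' a stage to each valid day from the surveys, computes prior-stage
#' baselines, evaluates the stage rule on every valid day, and labels
#' each stage under the configured policy.
#'
#' @param days `daily_summary` data frame for the participant
#'   (wear-masked, all days).
#' @param surveys Survey data frame for the participant.
#' @param config Pipeline configuration.
#' @return Data frame with one row per stage 1--3: `stage`,
#'   `n_valid_days`, `n_adherent_days`, `label`, plus attribute
#'   `verdicts` (per-stage list of per-day results).
#' @export
participant_adherence <- function(days, surveys, config = default_config()) {
  valid <- days[days$valid, , drop = FALSE]
  stage_of <- if (nrow(valid) > 0) {
    assign_stage_days(valid$date, surveys)$stage
  } else integer(0)
  fallback <- config$baseline$fallback
  baselines <- list()
  verdict_log <- list()
  rows <- vector("list", 3)
  for (s in 1:3) {
    sel <- which(stage_of == s)
    stage_days <- valid[sel, , drop = FALSE]
    baseline <- if (s == 1) NULL else {
      prior <- valid[stage_of == s - 1, , drop = FALSE]
      compute_baseline(prior, fallback, source_stage = s - 1L)
    }
    baselines[[s]] <- baseline
    verdicts <- lapply(seq_len(nrow(stage_days)), function(i) {
      evaluate_stage_day(s, stage_days[i, , drop = FALSE], baseline, config)
    })
    adherent <- vapply(verdicts, `[[`, logical(1), "adherent")
    lab <- label_participant_stage(adherent, config$policy$mode,
                                   config$policy$fraction)
    verdict_log[[s]] <- data.frame(
      date = stage_days$date,
      adherent = adherent,
      violations = vapply(verdicts, function(v)
        paste(v$violations, collapse = ";"), character(1)))
    rows[[s]] <- data.frame(stage = s, n_valid_days = lab$n_valid_days,
                            n_adherent_days = lab$n_adherent_days,
                            label = lab$label, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "verdicts") <- verdict_log
  attr(out, "baselines") <- baselines
  out
}
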