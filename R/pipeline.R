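#' Process one participant end to end
#'
#' Runs the objective chain (non-wear detection unioned with the
#' participant's wear log, wear masking, daily summaries, stage 1--3
#' adherence) and the subjective chain (symptom-free zero-imputation,
#' self-report labels) for a single participant.
#'
#' @param series Raw [epoch_series()] for the participant.
#' @param wearlog Wear-log data frame rows for this participant (may be
#'   empty); combined with algorithmic zero-run detection.
#' @param surveys Survey data frame rows for this participant.
#' @param config Pipeline configuration from [default_config()].
#' @return List: `days` (`daily_summary`), `adherence` (per-stage
#'   results), `objective_label`, `selfreport` (list `rta`, `rts`,
#'   `combined`).
#' @export
process_participant <- function(series, wearlog, surveys,
                                config = default_config()) {
  if (series$epoch_length != config$epoch_length_s) {
    series <- reaggregate_epochs(series, config$epoch_length_s)
  }
  thr <- intensity_thresholds(config$thresholds$sedentary_max,
                              config$thresholds$light_max,
                              config$thresholds$moderate_max,
                              epoch_length = config$epoch_length_s)
  algo <- detect_nonwear(series, config$nonwear$zero_run_min)
  log <- rbind(algo[, c("start", "end", "source")],
               if (!is.null(wearlog) && nrow(wearlog) > 0) {
                 wearlog[, c("start", "end", "source")]
               })
  masked <- apply_wear_mask(series, log)
  days <- summarize_days(masked, thr, config$valid_day$min_min,
                         config$valid_day$max_min)
  adh <- participant_adherence(days, surveys, config)
  objective <- if (any(adh$label == "Adhered")) {
    "Adhered"
  } else if (any(adh$label == "Did not adhere")) {
    "Did not adhere"
  } else {
    "Insufficient data"
  }
  imputed <- impute_pcss_zero_all(surveys)
  rta <- label_self_report(imputed, "rta", config$selfreport$pcss_rule)
  rts <- label_self_report(imputed, "rts", config$selfreport$pcss_rule)
  list(days = days, adherence = adh, objective_label = objective,
       selfreport = list(rta = rta, rts = rts,
                         combined = combine_labels(rta, rts)))
}

#' Score an in-memory simulated cohort
#'
#' Convenience wrapper running [process_participant()] over a cohort
#' from [simulate_cohort()] without touching the filesystem.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param config Pipeline configuration.
#' @return Data frame with one row per participant: `participant_id`,
#'   `stage1`/`stage2`/`stage3` labels, `objective_label`,
#'   `selfreport_rta`, `selfreport_rts`, `selfreport_combined`.
#' @export
score_cohort <- function(cohort, config = default_config()) {
  rows <- lapply(cohort$participants, function(p) {
    r <- process_participant(p$epochs, p$wearlog, p$surveys, config)
    data.frame(participant_id = p$truth$participant_id,
               stage1 = r$adherence$label[1],
               stage2 = r$adherence$label[2],
               stage3 = r$adherence$label[3],
               objective_label = r$objective_label,
               selfreport_rta = r$selfreport$rta,
               selfreport_rts = r$selfreport$rts,
               selfreport_combined = r$selfreport$combined,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

label_counts <- function(labels) {
  c(adhered = sum(labels == "Adhered"),
    did_not = sum(labels == "Did not adhere"),
    insufficient = sum(labels == "Insufficient data"))
}

comparison_row <- function(values, groups, protocol, outcome) {
  a <- values[groups == "Adhered" & !is.na(values)]
  b <- values[groups == "Did not adhere" & !is.na(values)]
  if (length(a) == 0 || length(b) == 0) return(NULL)
  mw <- mann_whitney_u(a, b, mode = "auto")
  data.frame(protocol = protocol, outcome = outcome,
             n_adhered = mw$n_a, n_did_not_adhere = mw$n_b,
             median_adhered = mw$median_a, median_did_not_adhere = mw$median_b,
             mean_rank_adhered = round(mw$mean_rank_a, 2),
             mean_rank_did_not_adhere = round(mw$mean_rank_b, 2),
             u_statistic = mw$u_statistic, p_value = mw$p_value,
             stringsAsFactors = FALSE)
}

#' Assemble cohort-level results from per-participant scores
#'
#' Builds the four study-style summaries: per-stage objective adherence
#' counts, self-report adherence counts, the 2x2 objective-vs-subjective
#' agreement with percent agreement and Cohen's kappa, and Mann-Whitney
#' comparisons of recovery outcomes between self-reported adherent and
#' non-adherent groups, plus the cohort reinjury rate.
#'
#' @param scores Data frame from [score_cohort()] (rows may also carry
#'   an `excluded_reason` column for participants that never reached
#'   scoring).
#' @param roster Cohort roster data frame.
#' @param surveys All-participant survey data frame.
#' @param config Pipeline configuration.
#' @return A `results_bundle` list: `stage_table`, `selfreport_table`,
#'   `agreement`, `comparisons`, `reinjury`, `exclusions`.
#' @export
assemble_results <- function(scores, roster, surveys,
                             config = default_config()) {
  n_cohort <- nrow(roster)

  stage_table <- do.call(rbind, lapply(1:3, function(s) {
    labels <- scores[[paste0("stage", s)]]
    cc <- label_counts(labels)
    n_elig <- cc[["adhered"]] + cc[["did_not"]]
    data.frame(stage = s,
               n_eligible = n_elig,
               n_adhered = cc[["adhered"]],
               n_did_not_adhere = cc[["did_not"]],
               n_excluded = n_cohort - n_elig,
               pct_adhered = if (n_elig > 0)
                 round(100 * rate(cc[["adhered"]], n_elig)) else NA_real_)
  }))

  selfreport_table <- do.call(rbind, lapply(
    c("rta", "rts", "combined"), function(proto) {
      labels <- scores[[paste0("selfreport_", proto)]]
      cc <- label_counts(labels)
      n_lab <- cc[["adhered"]] + cc[["did_not"]]
      data.frame(protocol = proto,
                 n_adhered = cc[["adhered"]],
                 n_did_not_adhere = cc[["did_not"]],
                 n_insufficient = n_cohort - n_lab,
                 pct_adhered = if (n_lab > 0)
                   round(100 * rate(cc[["adhered"]], n_lab)) else NA_real_)
    }))

  both <- scores$objective_label %in% c("Adhered", "Did not adhere") &
    scores$selfreport_rta %in% c("Adhered", "Did not adhere")
  agreement <- NULL
  if (any(both)) {
    obj <- scores$objective_label[both] == "Adhered"
    self <- scores$selfreport_rta[both] == "Adhered"
    tab <- contingency_2x2(sum(self & obj), sum(self & !obj),
                           sum(!self & obj), sum(!self & !obj))
    kap <- tryCatch(cohens_kappa(tab), error = function(e) NULL)
    agreement <- list(
      table = tab, n = attr(tab, "n"),
      percent_agreement = round(100 * percent_agreement(tab)),
      pct_self_only = round(100 * rate(tab$b, attr(tab, "n"))),
      kappa = kap)
  }

  outcomes <- lapply(seq_len(nrow(roster)), function(i) {
    svy <- surveys[surveys$participant_id == roster$participant_id[i], ,
                   drop = FALSE]
    recovery_outcome(roster[i, , drop = FALSE], svy,
                     config$selfreport$horizon_days)
  })
  ids <- vapply(outcomes, `[[`, character(1), "participant_id")
  m <- match(scores$participant_id, ids)
  days_res <- vapply(outcomes, function(o)
    if (is.na(o$days_to_resolution)) NA_real_
    else as.numeric(o$days_to_resolution), numeric(1))[m]
  pcss_res <- vapply(outcomes, function(o)
    as.numeric(o$pcss_at_resolution), numeric(1))[m]
  comparisons <- do.call(rbind, Filter(Negate(is.null), list(
    comparison_row(days_res, scores$selfreport_rta, "rta",
                   "days_to_resolution"),
    comparison_row(days_res, scores$selfreport_rts, "rts",
                   "days_to_resolution"),
    comparison_row(pcss_res, scores$selfreport_rta, "rta",
                   "pcss_at_resolution"),
    comparison_row(pcss_res, scores$selfreport_rts, "rts",
                   "pcss_at_resolution"))))

  resolved <- days_res[!is.na(days_res)]
  structure(list(
    n_cohort = n_cohort,
    stage_table = stage_table,
    selfreport_table = selfreport_table,
    agreement = agreement,
    comparisons = comparisons,
    resolution_summary = if (length(resolved) > 0) median_iqr(resolved),
    reinjury = list(n = sum(roster$reinjured), n_cohort = n_cohort,
                    pct = if (n_cohort > 0)
                      round(100 * rate(sum(roster$reinjured), n_cohort), 1)
                    else NA_real_),
    exclusions = if (!is.null(scores$excluded_reason)) {
      scores[!is.na(scores$excluded_reason),
             c("participant_id", "excluded_reason")]
    } else {
      data.frame(participant_id = character(0),
                 excluded_reason = character(0))
    }), class = "results_bundle")
}

#' Write the study-style result tables to a directory
#'
#' Emits `stage_adherence.csv` (per-stage adhered / did-not-adhere /
#' excluded counts), `selfreport_adherence.csv`, `agreement.csv` (the
#' 2x2 cells with percent agreement and kappa) and
#' `group_comparisons.csv` (medians, mean ranks, U and p per outcome),
#' plus the whole bundle as `report.json`.  An empty cohort writes
#' all-zero tables.
#'
#' @param results A `results_bundle` from [assemble_results()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_results_tables <- function(results, out_dir) {
  stopifnot(inherits(results, "results_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$stage_table,
                   file.path(out_dir, "stage_adherence.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(results$selfreport_table,
                   file.path(out_dir, "selfreport_adherence.csv"),
                   row.names = FALSE, quote = FALSE)
  ag <- results$agreement
  agreement_df <- if (is.null(ag)) {
    data.frame(a = 0, b = 0, c = 0, d = 0, n = 0,
               percent_agreement = NA, kappa = NA, ci_low = NA,
               ci_high = NA, p_value = NA)
  } else {
    data.frame(a = ag$table$a, b = ag$table$b, c = ag$table$c,
               d = ag$table$d, n = ag$n,
               percent_agreement = ag$percent_agreement,
               kappa = if (is.null(ag$kappa)) NA else ag$kappa$kappa,
               ci_low = if (is.null(ag$kappa)) NA else ag$kappa$ci_low,
               ci_high = if (is.null(ag$kappa)) NA else ag$kappa$ci_high,
               p_value = if (is.null(ag$kappa)) NA else ag$kappa$p_value)
  }
  utils::write.csv(agreement_df, file.path(out_dir, "agreement.csv"),
                   row.names = FALSE, quote = FALSE)
  comp <- results$comparisons
  if (is.null(comp)) {
    comp <- data.frame(protocol = character(0), outcome = character(0),
                       n_adhered = integer(0), n_did_not_adhere = integer(0),
                       median_adhered = numeric(0),
                       median_did_not_adhere = numeric(0),
                       mean_rank_adhered = numeric(0),
                       mean_rank_did_not_adhere = numeric(0),
                       u_statistic = numeric(0), p_value = numeric(0))
  }
  utils::write.csv(comp, file.path(out_dir, "group_comparisons.csv"),
                   row.names = FALSE, quote = FALSE)
  report <- results
  report$agreement$table <- if (!is.null(ag)) unclass(ag$table)[c("a", "b", "c", "d")]
  report$agreement$kappa <- if (!is.null(ag) && !is.null(ag$kappa))
    unclass(ag$kappa)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null", dataframe = "rows")
  invisible(out_dir)
}

#' Run the full pipeline over a dataset directory
#'
#' Orchestrates actigraphy processing, adherence scoring, self-report
#' labeling and the agreement/comparison statistics over a dataset laid
#' out as written by [simulate_cohort()]: `roster.csv`, `surveys.csv`,
#' `wearlog.csv` and `epochs/<participant_id>.csv`.  Participants
#' missing epoch or survey data are excluded with a structured,
#' machine-readable reason and still counted in the per-stage exclusion
#' denominators, so that adhered + did-not-adhere + excluded equals the
#' cohort size for every stage.  Outputs (tables, `report.json`,
#' `manifest.json`, `exclusions.log`) are byte-stable across repeated
#' runs on the same inputs.
#'
#' @param data_dir Input dataset directory.
#' @param out_dir Output directory for the report bundle.
#' @param config Pipeline configuration (see [default_config()] /
#'   [load_config()]).
#' @return The `results_bundle`, invisibly.
#' @export
run_all <- function(data_dir, out_dir, config = default_config()) {
  needed <- c(roster = "roster.csv", surveys = "surveys.csv",
              wearlog = "wearlog.csv", epochs = "epochs")
  for (kind in names(needed)) {
    if (!file.exists(file.path(data_dir, needed[[kind]]))) {
      stop(sprintf("missing input kind '%s' (%s) in %s", kind,
                   needed[[kind]], data_dir), call. = FALSE)
    }
  }
  roster <- read_roster_csv(file.path(data_dir, "roster.csv"))
  surveys <- read_survey_csv(file.path(data_dir, "surveys.csv"))
  wearlog <- read_wearlog_csv(file.path(data_dir, "wearlog.csv"))

  rows <- lapply(seq_len(nrow(roster)), function(i) {
    pid <- roster$participant_id[i]
    blank <- data.frame(participant_id = pid, stage1 = "Insufficient data",
                        stage2 = "Insufficient data",
                        stage3 = "Insufficient data",
                        objective_label = "Insufficient data",
                        selfreport_rta = "Insufficient data",
                        selfreport_rts = "Insufficient data",
                        selfreport_combined = "Insufficient data",
                        excluded_reason = NA_character_,
                        stringsAsFactors = FALSE)
    epo_path <- file.path(data_dir, "epochs", paste0(pid, ".csv"))
    if (!file.exists(epo_path)) {
      blank$excluded_reason <- "no_epoch_data"
      return(blank)
    }
    svy <- surveys[surveys$participant_id == pid, , drop = FALSE]
    if (nrow(svy) == 0) {
      blank$excluded_reason <- "no_survey_data"
      return(blank)
    }
    series <- read_epoch_csv(epo_path, participant_id = pid)
    wl <- wearlog[wearlog$participant_id == pid, , drop = FALSE]
    r <- process_participant(series, wl, svy, config)
    data.frame(participant_id = pid,
               stage1 = r$adherence$label[1], stage2 = r$adherence$label[2],
               stage3 = r$adherence$label[3],
               objective_label = r$objective_label,
               selfreport_rta = r$selfreport$rta,
               selfreport_rts = r$selfreport$rts,
               selfreport_combined = r$selfreport$combined,
               excluded_reason = if (r$objective_label == "Insufficient data")
                 "no_valid_days" else NA_character_,
               stringsAsFactors = FALSE)
  })
  scores <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(participant_id = character(0), stage1 = character(0),
               stage2 = character(0), stage3 = character(0),
               objective_label = character(0),
               selfreport_rta = character(0), selfreport_rts = character(0),
               selfreport_combined = character(0),
               excluded_reason = character(0), stringsAsFactors = FALSE)
  results <- assemble_results(scores, roster, surveys, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_tables(results, out_dir)

  excl <- results$exclusions
  excl <- excl[order(excl$participant_id), , drop = FALSE]
  writeLines(sprintf("excluded\t%s\t%s", excl$participant_id,
                     excl$excluded_reason),
             file.path(out_dir, "exclusions.log"))

  inputs <- sort(c(file.path(data_dir, needed[1:3]),
                   list.files(file.path(data_dir, "epochs"),
                              full.names = TRUE)))
  manifest <- list(
    tool = "actiadhere",
    version = as.character(utils::packageVersion("actiadhere")),
    config = config,
    inputs = lapply(inputs, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))),
    row_counts = list(roster = nrow(roster), surveys = nrow(surveys),
                      wearlog = nrow(wearlog),
                      scored = sum(is.na(scores$excluded_reason))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(results)
}
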