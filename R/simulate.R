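# Ground-truth cohort simulator.
#
# Counts are drawn uniformly *within* the configured intensity band of the
# intended class, so every simulated epoch classifies exactly as intended
# and per-day class minutes are known by construction.  Sedentary draws
# start at 1 count so that true non-wear (exact zeros) is unambiguous to
# the zero-run detector.  Adherent-flagged participant-stages satisfy the
# stage rule with a safety margin on every day; non-adherent ones carry an
# explicit, logged violation on every day of that stage.

#' Simulation configuration
#'
#' Returns the full set of generator parameters.  Defaults encode the
#' study conditions the pipeline is meant to operate under: a 48-hour
#' survey cadence, a baseline symptom score with median 36 (IQR 17--56),
#' per-stage objective adherent fractions of 13\%/11\%/34\%, recovery
#' times with medians 13 days (self-reported adherent) and 20 days
#' (non-adherent), a 14\% chance of never resolving within the 180-day
#' horizon, a reinjury probability of 3/139, and self-report labels that
#' agree with the objective label only at chance level
#' (`selfreport_discordance = 0.5`).
#'
#' @param n_participants Cohort size.
#' @param seed Master seed; all randomness derives from it.
#' @param overrides Named list of fields to override.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 20, seed = 1, overrides = list()) {
  cfg <- list(
    n_participants = n_participants,
    seed = seed,
    epoch_length_s = 30,
    stage_duration_days = c(4, 4, 5, 6, 7, 14),      # RTA stages 1-6 (mean)
    rts_stage_duration_days = c(3, 4, 5, 6, 10),     # RTS stages 1-5 (mean)
    adherent_fraction = c(stage1 = 0.133, stage2 = 0.108, stage3 = 0.34),
    pcss_start = list(median = 36, q1 = 17, q3 = 56),
    pcss_decay_halflife = 5,
    pcss_noise_max = 3,
    dichotomous_fraction = 0.1,
    resolution_median_days = c(adhered = 13, nonadhered = 20),
    resolution_sdlog = 0.7,
    nonresolution_probability = 16 / 114,
    selfreport_discordance = 0.5,
    rts_adherent_fraction = 0.533,
    nonwear_rate = 0.15,
    survey_interval_hours = 48,
    reinjury_probability = 3 / 139,
    withdraw_probability = 0,
    horizon_days = 180,
    activity_profile = list(
      lpa_run_min = 4, mvpa_run_min = 2,
      stage1 = list(lpa = 60, mvpa = 8),
      stage2 = list(extra_lpa = 15),
      stage3 = list(extra_mvpa = 40, long_bouts = c(12, 12)),
      violations = list(
        stage1 = c("mvpa_cap", "bout"),
        stage2 = c("lpa_cap", "mvpa_bout"),
        stage3 = c("mvpa_cap", "bout_count", "bout_length")))
  )
  cfg <- merge_config(cfg, overrides)
  cfg$n_participants <- n_participants
  cfg$seed <- seed
  structure(cfg, class = "sim_config")
}

participant_seed <- function(master, index) {
  as.integer((as.numeric(master) * 1000003 + index * 7919) %% 2147483647)
}

draw_counts <- function(n, lo, hi) {
  if (n == 0) return(integer(0))
  as.integer(lo + floor(stats::runif(n) * (hi - lo + 1)))
}

# assemble one day's 2880-epoch count vector from class-minute targets
build_sim_day <- function(targets, thr, wear_start_min, wear_end_min,
                          gap_min = NULL) {
  ep_per_min <- 60 / thr$epoch_length
  n_day <- as.integer(86400 / thr$epoch_length)
  blocks <- list()
  add_block <- function(class, minutes) {
    n_ep <- round(minutes * ep_per_min)
    if (n_ep >= 1) blocks[[length(blocks) + 1]] <<-
        list(class = class, n = n_ep)
  }
  run_l <- targets$lpa_run_min
  run_m <- targets$mvpa_run_min
  lpa <- targets$lpa_scatter_min
  while (lpa > 0) { add_block("light", min(run_l, lpa)); lpa <- lpa - run_l }
  for (b in targets$lpa_bouts_min) add_block("light", b)
  mvpa <- targets$mvpa_scatter_min
  while (mvpa > 0) { add_block("mvpa", min(run_m, mvpa)); mvpa <- mvpa - run_m }
  for (b in targets$mvpa_bouts_min) add_block("mvpa", b)
  if (!is.null(gap_min)) add_block("zero", gap_min)

  blocks <- blocks[sample.int(length(blocks))]
  worn <- as.integer((wear_end_min - wear_start_min) * ep_per_min)
  act <- sum(vapply(blocks, `[[`, numeric(1), "n"))
  nb <- length(blocks)
  sed_total <- worn - act
  if (sed_total < 2 * (nb + 1)) {
    stop("simulated day over-full: activity targets exceed wear window",
         call. = FALSE)
  }
  alloc <- 2 + as.integer(stats::rmultinom(1, sed_total - 2 * (nb + 1),
                                           rep(1, nb + 1)))
  counts <- integer(n_day)
  pos <- as.integer(wear_start_min * ep_per_min) + 1L
  emit <- function(v) {
    counts[pos:(pos + length(v) - 1L)] <<- v
    pos <<- pos + length(v)
  }
  for (i in seq_len(nb + 1)) {
    emit(draw_counts(alloc[i], 1, thr$sedentary_max))
    if (i <= nb) {
      b <- blocks[[i]]
      if (b$class == "light") {
        emit(draw_counts(b$n, thr$sedentary_max + 1, thr$light_max))
      } else if (b$class == "mvpa") {
        vig <- stats::runif(b$n) < 0.15
        v <- integer(b$n)
        v[!vig] <- draw_counts(sum(!vig), thr$light_max + 1, thr$moderate_max)
        v[vig] <- draw_counts(sum(vig), thr$moderate_max + 1,
                              thr$moderate_max + 1500)
        emit(v)
      } else {
        emit(integer(b$n))  # in-window non-wear
      }
    }
  }
  gap_len <- if (is.null(gap_min)) 0 else gap_min
  list(counts = counts,
       realized = list(
         lpa = targets$lpa_scatter_min + sum(targets$lpa_bouts_min),
         mvpa = targets$mvpa_scatter_min + sum(targets$mvpa_bouts_min),
         wear = wear_end_min - wear_start_min - gap_len))
}

stage_targets <- function(stage, adherent, violation, profile, base_lpa,
                          base_mvpa) {
  t <- list(lpa_run_min = profile$lpa_run_min,
            mvpa_run_min = profile$mvpa_run_min,
            lpa_scatter_min = 0, lpa_bouts_min = numeric(0),
            mvpa_scatter_min = 0, mvpa_bouts_min = numeric(0))
  if (stage == 1) {
    t$lpa_scatter_min <- profile$stage1$lpa
    t$mvpa_scatter_min <- profile$stage1$mvpa
    if (!adherent) {
      if (violation == "mvpa_cap") {
        t$mvpa_scatter_min <- 35            # > 2.5% of any valid wear time
      } else {                              # "bout"
        t$lpa_scatter_min <- t$lpa_scatter_min - 8
        t$lpa_bouts_min <- 8
      }
    }
  } else if (stage == 2) {
    t$lpa_scatter_min <- base_lpa + profile$stage2$extra_lpa
    t$mvpa_scatter_min <- base_mvpa
    if (!adherent) {
      if (violation == "lpa_cap") {
        t$lpa_scatter_min <- base_lpa + 60
      } else {                              # "mvpa_bout"
        t$mvpa_bouts_min <- 8
      }
    }
  } else {
    t$lpa_scatter_min <- base_lpa
    if (adherent) {
      t$mvpa_bouts_min <- profile$stage3$long_bouts
      t$mvpa_scatter_min <- max(0, base_mvpa + profile$stage3$extra_mvpa -
                                  sum(t$mvpa_bouts_min))
    } else if (violation == "mvpa_cap") {
      t$mvpa_scatter_min <- base_mvpa + 90
    } else if (violation == "bout_count") {
      t$mvpa_bouts_min <- c(8, 8, 8)
      t$mvpa_scatter_min <- base_mvpa
    } else {                                # "bout_length"
      t$mvpa_bouts_min <- 20
      t$mvpa_scatter_min <- base_mvpa
    }
  }
  t
}

#' Simulate one participant
#'
#' Draws the participant's ground truth (stage timeline, per-stage
#' objective adherence with an explicit violation code when
#' non-adherent, symptom trajectory, self-report labels, recovery and
#' reinjury) and emits the four input artefacts the pipeline reads.
#' Accelerometry covers injury day through the end of RTA stage 3, the
#' phase the objective rules apply to.
#'
#' @param config A [sim_config()].
#' @param index Participant index (1-based); the per-participant seed is
#'   derived from the master seed and this index.
#' @return List with `epochs` ([epoch_series()]), `wearlog`, `surveys`,
#'   `roster` (one-row data frames) and `truth` (ground-truth list).
#' @export
simulate_participant <- function(config, index) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(participant_seed(config$seed, index))
  pid <- sprintf("P%03d", index)
  thr <- evenson_thresholds(config$epoch_length_s)
  profile <- config$activity_profile

  injury_date <- as.Date("2024-03-01") + (index * 13) %% 60
  injury_dt <- as.POSIXct(paste0(format(injury_date), " ",
                                 sprintf("%02d:%02d:00",
                                         8 + sample(0:9, 1), sample(0:59, 1))),
                          tz = ACTI_TZ)

  # symptom baseline: lognormal matched to median 36, IQR 17-56
  ps <- config$pcss_start
  sdlog <- log(ps$q3 / ps$q1) / (2 * stats::qnorm(0.75))
  s0 <- round(stats::rlnorm(1, log(ps$median), sdlog))
  form <- if (stats::runif(1) < config$dichotomous_fraction) "dichotomous"
          else "likert"
  form_max <- if (form == "likert") 132L else 22L
  if (form == "dichotomous") s0 <- round(s0 * 22 / 132)
  s0 <- max(0, min(form_max, s0))

  # intended labels
  adherent <- stats::runif(3) < config$adherent_fraction
  names(adherent) <- paste0("stage", 1:3)
  viol <- vapply(1:3, function(s) {
    if (adherent[s]) NA_character_
    else sample(profile$violations[[paste0("stage", s)]], 1)
  }, character(1))
  objective_overall <- any(adherent)
  self_rta <- if (stats::runif(1) < config$selfreport_discordance) {
    !objective_overall
  } else objective_overall
  self_rts <- stats::runif(1) < config$rts_adherent_fraction

  resolved <- stats::runif(1) >= config$nonresolution_probability
  med <- config$resolution_median_days[[if (self_rta) "adhered"
                                         else "nonadhered"]]
  resolution_days <- if (resolved) {
    max(4, min(config$horizon_days,
               round(stats::rlnorm(1, log(med), config$resolution_sdlog))))
  } else NA_integer_
  span <- if (resolved) resolution_days else config$horizon_days

  # stage timelines (durations >= 1 day, Poisson-jittered around the mean)
  rta_dur <- 1 + stats::rpois(6, pmax(0, config$stage_duration_days - 1))
  rts_dur <- 1 + stats::rpois(5, pmax(0, config$rts_stage_duration_days - 1))
  rta_start <- cumsum(c(0, rta_dur[-6]))       # day each stage begins
  rts_start <- cumsum(c(0, rts_dur[-5]))
  stage_at <- function(day, starts) findInterval(day, starts)

  # --- surveys every survey_interval hours, plus the resolution visit ---
  # surveys continue past symptom resolution until the protocols complete,
  # so stage data exists through RTA stage 6 / RTS stage 5
  step <- config$survey_interval_hours / 24
  survey_end <- min(config$horizon_days,
                    max(span, rta_start[6] + 2, rts_start[5] + 2))
  days <- seq(0, survey_end, by = step)
  if (resolved && !span %in% days) days <- sort(c(days, span))
  halflife <- if (resolved) span / log2(max(s0, 4)) else
    config$pcss_decay_halflife * 18          # slow decay, never resolves
  raw <- s0 * 2^(-days / halflife)
  noise <- sample(-config$pcss_noise_max:config$pcss_noise_max,
                  length(days), replace = TRUE)
  pcss <- pmin(form_max, pmax(0L, as.integer(round(raw) + noise)))
  symptom_free <- resolved & days >= span
  rta_rep <- pmin(6L, stage_at(days, rta_start))
  rts_rep <- pmin(5L, stage_at(days, rts_start))

  # report a stage one below the previously reported stage at one survey,
  # guaranteeing a regression while staying in the legal stage range
  inject_regression <- function(stages) {
    m <- which(stages >= 2)
    m <- m[m < length(stages)]
    if (length(m) == 0) return(NULL)
    i <- m[1]
    stages[i + 1] <- stages[i] - 1L
    stages
  }
  pcss_bump <- FALSE
  if (!self_rta) {
    reg <- inject_regression(rta_rep)
    if (!is.null(reg)) rta_rep <- reg else pcss_bump <- TRUE
  }
  if (!self_rts) {
    reg <- inject_regression(rts_rep)
    if (!is.null(reg)) rts_rep <- reg else pcss_bump <- TRUE
  }
  if (pcss_bump) {
    # no stage regression available within the survey span: realise
    # non-adherence through a rising symptom endpoint instead (affects
    # both protocol labels, so intents are reconciled below)
    pcss[length(pcss)] <- min(form_max, pcss[1] + 5L)
    symptom_free[length(symptom_free)] <- FALSE
    self_rta <- FALSE
    self_rts <- FALSE
  } else {
    last_eff <- if (symptom_free[length(pcss)]) 0L else pcss[length(pcss)]
    if ((self_rta || self_rts) && last_eff > pcss[1]) {
      pcss[length(pcss)] <- pcss[1]
    }
  }
  surveys <- data.frame(
    participant_id = pid,
    date = injury_date + days,
    pcss_total = pcss,
    pcss_form = form,
    rta_stage = rta_rep,
    rts_stage = rts_rep,
    cognitive_level = pmin(5L, rts_rep),
    symptom_free = symptom_free,
    stringsAsFactors = FALSE)

  # --- accelerometry: worn while the protocol is in stages 1-3 ---
  # Each day is built for the stage the scoring engine will assign it:
  # the carry-forward of the *reported* stage sequence (including any
  # injected regression).  This keeps intended per-stage flags
  # recoverable by construction.
  all_days <- 0:survey_end
  eng <- rta_rep[findInterval(all_days, days)]
  past3 <- which(eng >= 4)
  acc_days <- if (length(past3) > 0) as.integer(all_days[past3[1]]) else
    as.integer(min(span, survey_end)) + 1L
  day_stage <- eng[seq_len(acc_days)]

  fallback <- default_config()$baseline$fallback
  counts_all <- vector("list", acc_days)
  real_lpa <- numeric(acc_days)
  real_mvpa <- numeric(acc_days)
  wearlog <- list()
  for (s in 1:3) {
    sel <- which(day_stage == s)
    if (length(sel) == 0) next
    if (s == 1) {
      base_lpa <- NA_real_; base_mvpa <- NA_real_
    } else {
      prior <- which(day_stage == s - 1)
      if (length(prior) > 0) {
        base_lpa <- mean(real_lpa[prior])
        base_mvpa <- mean(real_mvpa[prior])
      } else {
        # mirrors the engine's configured fallback baseline
        base_lpa <- fallback$lpa
        base_mvpa <- fallback$mvpa
      }
    }
    targets <- stage_targets(s, adherent[s], viol[s], profile,
                             base_lpa, base_mvpa)
    for (i in sel) {
      d <- i - 1L
      wear_start <- 420 + sample(0:60, 1)        # 07:00-08:00
      wear_end <- 1230 + sample(0:60, 1)         # 20:30-21:30
      gap <- NULL
      if (stats::runif(1) < config$nonwear_rate) gap <- sample(65:120, 1)
      day <- build_sim_day(targets, thr, wear_start, wear_end, gap)
      counts_all[[i]] <- day$counts
      real_lpa[i] <- day$realized$lpa
      real_mvpa[i] <- day$realized$mvpa
      if (!is.null(gap) && stats::runif(1) < 0.5) {
        # participant remembered to log this gap; locate the zero run
        z <- rle(day$counts == 0)
        ends <- cumsum(z$lengths); starts <- ends - z$lengths + 1
        inwin <- which(z$values &
                         starts > wear_start * 2 & ends <= wear_end * 2)
        if (length(inwin) > 0) {
          j <- inwin[which.max(z$lengths[inwin])]
          day0 <- as.POSIXct(paste(format(injury_date + d), "00:00:00"),
                             tz = ACTI_TZ)
          wearlog[[length(wearlog) + 1]] <- data.frame(
            participant_id = pid,
            start = day0 + (starts[j] - 1) * thr$epoch_length,
            end = day0 + ends[j] * thr$epoch_length,
            source = "participant_log", stringsAsFactors = FALSE)
        }
      }
    }
  }
  ts0 <- as.POSIXct(paste(format(injury_date), "00:00:00"), tz = ACTI_TZ)
  n_per_day <- as.integer(86400 / thr$epoch_length)
  timestamps <- ts0 + as.numeric(outer(seq_len(n_per_day) - 1,
                                       seq_len(acc_days) - 1,
                                       function(i, d) d * 86400 +
                                         i * thr$epoch_length))
  epochs <- epoch_series(timestamps, unlist(counts_all),
                         epoch_length = thr$epoch_length,
                         participant_id = pid, require_uniform = TRUE)
  wearlog <- if (length(wearlog) > 0) do.call(rbind, wearlog) else
    data.frame(participant_id = character(0),
               start = as.POSIXct(character(0), tz = ACTI_TZ),
               end = as.POSIXct(character(0), tz = ACTI_TZ),
               source = character(0), stringsAsFactors = FALSE)

  reinjured <- stats::runif(1) < config$reinjury_probability
  roster <- data.frame(
    participant_id = pid,
    injury_datetime = injury_dt,
    resolution_date = if (resolved) injury_date + resolution_days
                      else as.Date(NA),
    reinjured = reinjured,
    withdrew = stats::runif(1) < config$withdraw_probability,
    stringsAsFactors = FALSE)

  truth <- list(
    participant_id = pid,
    objective_flags = as.list(adherent),
    violation_codes = stats::setNames(as.list(viol), paste0("stage", 1:3)),
    objective_overall = objective_overall,
    selfreport_rta = if (self_rta) "Adhered" else "Did not adhere",
    selfreport_rts = if (self_rts) "Adhered" else "Did not adhere",
    selfreport_combined = if (self_rta && self_rts) "Adhered"
                          else "Did not adhere",
    pcss_start = s0,
    resolution_day = if (resolved) resolution_days else NA_integer_,
    censored = !resolved,
    reinjured = reinjured,
    rta_stage_start_days = rta_start,
    rts_stage_start_days = rts_start,
    accelerometry_days = acc_days)

  list(epochs = epochs, wearlog = wearlog, surveys = surveys,
       roster = roster, truth = truth)
}

#' Simulate a full study cohort
#'
#' Generates `config$n_participants` participants (seeds derived
#' deterministically from the master seed and the participant index) and
#' optionally writes the complete dataset directory in the exact CSV
#' schemas the readers expect: `epochs/<id>.csv`, `wearlog.csv`,
#' `surveys.csv`, `roster.csv` and a `groundtruth.json` manifest.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory, or `NULL` to keep the cohort in
#'   memory only.
#' @return Invisibly, a list with `participants` (per-participant lists
#'   from [simulate_participant()]) and `truth` (list of ground-truth
#'   records).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  participants <- lapply(seq_len(config$n_participants),
                         function(i) simulate_participant(config, i))
  truth <- lapply(participants, `[[`, "truth")
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "epochs"), recursive = TRUE,
               showWarnings = FALSE)
    for (p in participants) {
      write_epoch_csv(p$epochs, file.path(out_dir, "epochs",
                                          paste0(p$truth$participant_id,
                                                 ".csv")))
    }
    bind <- function(field) do.call(rbind, lapply(participants, `[[`, field))
    if (config$n_participants > 0) {
      write_wearlog_csv(bind("wearlog"), file.path(out_dir, "wearlog.csv"))
      write_survey_csv(bind("surveys"), file.path(out_dir, "surveys.csv"))
      write_roster_csv(bind("roster"), file.path(out_dir, "roster.csv"))
    } else {
      write_wearlog_csv(
        data.frame(participant_id = character(0),
                   start = as.POSIXct(character(0), tz = ACTI_TZ),
                   end = as.POSIXct(character(0), tz = ACTI_TZ),
                   source = character(0)),
        file.path(out_dir, "wearlog.csv"))
      utils::write.csv(data.frame(participant_id = character(0),
                                  date = character(0),
                                  pcss_total = integer(0),
                                  pcss_form = character(0),
                                  rta_stage = integer(0),
                                  rts_stage = integer(0),
                                  cognitive_level = integer(0),
                                  symptom_free = character(0)),
                       file.path(out_dir, "surveys.csv"), row.names = FALSE)
      utils::write.csv(data.frame(participant_id = character(0),
                                  injury_datetime = character(0),
                                  resolution_date = character(0),
                                  reinjured = character(0),
                                  withdrew = character(0)),
                       file.path(out_dir, "roster.csv"), row.names = FALSE)
    }
    jsonlite::write_json(truth, file.path(out_dir, "groundtruth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  invisible(list(participants = participants, truth = truth))
}
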