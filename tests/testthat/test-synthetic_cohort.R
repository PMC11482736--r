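test_that("simulation is deterministic given the master seed", {
  cfg <- sim_config(n_participants = 3, seed = 99)
  p1 <- simulate_participant(cfg, 2)
  p2 <- simulate_participant(cfg, 2)
  expect_identical(p1$epochs$counts, p2$epochs$counts)
  expect_identical(p1$surveys, p2$surveys)
  expect_identical(p1$truth, p2$truth)

  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$participants[[3]]$epochs$counts,
                   c2$participants[[3]]$epochs$counts)
})

test_that("an empty cohort writes an empty manifest and no epoch files", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(sim_config(n_participants = 0, seed = 1),
                        out_dir = dir)
  expect_length(co$truth, 0)
  expect_length(list.files(file.path(dir, "epochs")), 0)
  expect_equal(nrow(read_roster_csv(file.path(dir, "roster.csv"))), 0)
  expect_identical(jsonlite::read_json(file.path(dir, "groundtruth.json")),
                   list())
})

test_that("simulated counts classify exactly as intended and days are valid", {
  co <- simulate_cohort(sim_config(n_participants = 4, seed = 5))
  thr <- evenson_thresholds(30)
  for (p in co$participants) {
    r <- process_participant(p$epochs, p$wearlog, p$surveys)
    expect_true(all(r$days$valid))
    # wear inside the simulated on-body window
    expect_true(all(r$days$wear_minutes >= 600 &
                      r$days$wear_minutes <= 900))
  }
})

test_that("adherent-flagged participants adhere on every valid day", {
  cfg <- sim_config(n_participants = 5, seed = 21,
                    overrides = list(adherent_fraction =
                                       c(stage1 = 1, stage2 = 1, stage3 = 1)))
  co <- simulate_cohort(cfg)
  for (p in co$participants) {
    r <- process_participant(p$epochs, p$wearlog, p$surveys)
    verdicts <- attr(r$adherence, "verdicts")
    for (s in 1:3) {
      expect_true(all(verdicts[[s]]$adherent),
                  info = paste(p$truth$participant_id, "stage", s))
    }
    expect_equal(r$objective_label, "Adhered")
  }
})

test_that("non-adherent participants violate their injected clause daily", {
  cfg <- sim_config(n_participants = 5, seed = 22,
                    overrides = list(adherent_fraction =
                                       c(stage1 = 0, stage2 = 0, stage3 = 0)))
  co <- simulate_cohort(cfg)
  for (p in co$participants) {
    r <- process_participant(p$epochs, p$wearlog, p$surveys)
    verdicts <- attr(r$adherence, "verdicts")
    for (s in 1:3) {
      v <- verdicts[[s]]
      if (nrow(v) == 0) next  # stage skipped between surveys
      expect_true(all(!v$adherent))
      code <- p$truth$violation_codes[[paste0("stage", s)]]
      expect_true(all(grepl(code, v$violations, fixed = TRUE)),
                  info = paste(p$truth$participant_id, s, code))
    }
  }
})

test_that("symptom trajectories decay from the drawn baseline to resolution", {
  co <- simulate_cohort(sim_config(n_participants = 10, seed = 31))
  for (p in co$participants) {
    svy <- p$surveys
    expect_true(all(svy$pcss_total >= 0))
    limit <- if (svy$pcss_form[1] == "likert") 132 else 22
    expect_true(all(svy$pcss_total <= limit))
    # first report sits within rounding + noise of the drawn start score
    expect_lte(abs(svy$pcss_total[1] - p$truth$pcss_start), 4)
    if (!p$truth$censored) {
      res_date <- p$roster$resolution_date
      at <- impute_pcss_zero_all(svy)
      expect_equal(at$pcss_total[max(which(at$date <= res_date))], 0L)
    }
  }
})

test_that("derived self-report labels equal the generator's intent", {
  co <- simulate_cohort(sim_config(n_participants = 20, seed = 8))
  sc <- score_cohort(co)
  expect_equal(sc$selfreport_rta,
               vapply(co$truth, `[[`, "", "selfreport_rta"))
  expect_equal(sc$selfreport_rts,
               vapply(co$truth, `[[`, "", "selfreport_rts"))
  expect_equal(sc$selfreport_combined,
               vapply(co$truth, `[[`, "", "selfreport_combined"))
})

test_that("the engine recovers intended stage flags at a 50% mix", {
  cfg <- sim_config(n_participants = 40, seed = 77,
                    overrides = list(adherent_fraction =
                                       c(stage1 = 0.5, stage2 = 0.5,
                                         stage3 = 0.5)))
  co <- simulate_cohort(cfg)
  sc <- score_cohort(co)
  hits <- 0; insuff <- 0
  for (s in 1:3) {
    want <- vapply(co$truth, function(t)
      t$objective_flags[[paste0("stage", s)]], logical(1))
    got <- sc[[paste0("stage", s)]]
    hits <- hits + sum(got == ifelse(want, "Adhered", "Did not adhere"))
    insuff <- insuff + sum(got == "Insufficient data")
  }
  expect_gte(hits / 120, 0.95)
  # recovered adherent fraction within binomial 99% bounds of 0.5
  n_adh <- sum(sc$stage1 == "Adhered") + sum(sc$stage2 == "Adhered") +
    sum(sc$stage3 == "Adhered")
  n_lab <- 120 - insuff
  expect_gte(n_adh, qbinom(0.005, n_lab, 0.5))
  expect_lte(n_adh, qbinom(0.995, n_lab, 0.5))
})

test_that("pipeline agreement tracks the intended label agreement", {
  co <- simulate_cohort(sim_config(n_participants = 150, seed = 12))
  sc <- score_cohort(co)
  roster <- do.call(rbind, lapply(co$participants, `[[`, "roster"))
  surveys <- do.call(rbind, lapply(co$participants, `[[`, "surveys"))
  res <- assemble_results(sc, roster, surveys)

  truth_obj <- vapply(co$truth, `[[`, TRUE, "objective_overall")
  truth_self <- vapply(co$truth, `[[`, "", "selfreport_rta") == "Adhered"
  t_int <- contingency_2x2(sum(truth_self & truth_obj),
                           sum(truth_self & !truth_obj),
                           sum(!truth_self & truth_obj),
                           sum(!truth_self & !truth_obj))
  k_int <- cohens_kappa(t_int)
  k_pipe <- res$agreement$kappa
  # near-perfect label recovery keeps the pipeline kappa at the intended one
  expect_lt(abs(k_pipe$kappa - k_int$kappa), 0.06)
  # intended discordance 0.5 means chance-level agreement
  expect_lt(abs(k_int$kappa), 3 * k_int$se)
})
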