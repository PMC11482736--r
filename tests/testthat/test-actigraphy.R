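test_that("reaggregation sums counts in aligned windows", {
  s <- make_series(c(10, 20, 30), epoch_len = 10)
  expect_equal(reaggregate_epochs(s, 30)$counts, 60L)

  s <- make_series(c(5, 5, 5, 5, 5, 5), epoch_len = 15)
  expect_equal(reaggregate_epochs(s, 30)$counts, c(10L, 10L, 10L))

  s30 <- make_series(c(1, 2, 3))
  expect_identical(reaggregate_epochs(s30, 30), s30)
  expect_error(reaggregate_epochs(make_series(1:4, epoch_len = 15), 20),
               "not a multiple")
})

test_that("reaggregation conserves total counts when windows divide evenly", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      k <- sample(c(2, 3, 6), 1)
      n <- k * sample(5:40, 1)
      s <- make_series(sample(0:500, n, replace = TRUE), epoch_len = 5)
      agg <- reaggregate_epochs(s, 5 * k)
      expect_equal(sum(agg$counts), sum(s$counts))
    }
  })
})

test_that("zero-run non-wear detection honours the duration threshold", {
  expect_equal(nrow(detect_nonwear(make_series(rep(10, 100)), 60)), 0)

  s <- make_series(c(rep(5, 10), rep(0, 120), rep(5, 10)))
  nw <- detect_nonwear(s, 60)
  expect_equal(nrow(nw), 1)
  expect_equal(as.numeric(nw$end - nw$start, units = "mins"), 60)

  s <- make_series(c(rep(5, 10), rep(0, 118), rep(5, 10)))
  expect_equal(nrow(detect_nonwear(s, 60)), 0)
})

test_that("non-wear detection matches a brute-force zero-run scan", {
  withr::with_seed(23, {
    for (rep in 1:25) {
      counts <- integer(0)
      while (length(counts) < 3000) {
        counts <- c(counts,
                    rep(sample(c(0L, sample(1:200, 1)), 1,
                               prob = c(0.4, 0.6)),
                        sample(c(5:50, 150), 1)))
      }
      s <- make_series(counts[1:3000])
      got <- detect_nonwear(s, 60)
      want <- brute_nonwear(s, 60)
      expect_equal(nrow(got), length(want))
      if (length(want) > 0) {
        expect_equal(as.numeric(got$start), vapply(want, `[[`, 0, "start"))
        expect_equal(as.numeric(got$end), vapply(want, `[[`, 0, "end"))
      }
    }
  })
})

test_that("wear masking removes overlapped epochs with union semantics", {
  s <- make_series(rep(1, 240))  # 2 h of 30-s epochs from midnight
  log <- data.frame(start = as.POSIXct("2024-01-01 00:00:00", tz = "UTC"),
                    end = as.POSIXct("2024-01-01 01:00:00", tz = "UTC"),
                    source = "participant_log")
  expect_length(apply_wear_mask(s, log), 120)
  expect_identical(apply_wear_mask(s, log[0, ]), s)

  # overlapping participant + algorithm intervals remove the union once
  log2 <- rbind(log, data.frame(
    start = as.POSIXct("2024-01-01 00:30:00", tz = "UTC"),
    end = as.POSIXct("2024-01-01 01:15:00", tz = "UTC"),
    source = "algorithm"))
  expect_length(apply_wear_mask(s, log2), 240 - 150)
})

test_that("cut-point classification respects inclusive boundaries", {
  thr <- evenson_thresholds(30)
  expect_equal(thr$sedentary_max, 50)
  expect_equal(thr$light_max, 1147)
  expect_equal(thr$moderate_max, 2005)
  expect_equal(classify_epoch(c(0, 50, 51, 1147, 1148, 2005, 2006), thr),
               c("sedentary", "sedentary", "light", "light", "moderate",
                 "moderate", "vigorous"))
  # per-minute scale
  thr60 <- evenson_thresholds(60)
  expect_equal(c(thr60$sedentary_max, thr60$light_max, thr60$moderate_max),
               c(100, 2295, 4011))
})

test_that("classification is monotone in counts", {
  thr <- evenson_thresholds(30)
  lv <- c(sedentary = 1, light = 2, moderate = 3, vigorous = 4)
  cl <- lv[classify_epoch(0:2500, thr)]
  expect_true(all(diff(cl) >= 0))
})

test_that("valid-day bounds are inclusive at 6 and 19 hours of wear", {
  thr <- evenson_thresholds(30)
  d <- summarize_days(make_series(rep(0, 720)), thr)   # 360 min
  expect_true(d$valid)
  expect_equal(d$wear_minutes, 360)
  expect_equal(d$sedentary_minutes, 360)

  expect_false(summarize_days(make_series(rep(0, 718)), thr)$valid)  # 359 min
  expect_false(summarize_days(make_series(rep(0, 2282)), thr)$valid[1]) # 1141
  expect_true(summarize_days(make_series(rep(0, 2280)), thr)$valid[1]) # 1140
})

test_that("class minutes always sum to wear minutes", {
  thr <- evenson_thresholds(30)
  withr::with_seed(31, {
    for (rep in 1:10) {
      n <- sample(500:4000, 1)
      s <- make_series(sample(0:3000, n, replace = TRUE),
                       start = as.POSIXct("2024-01-01 05:00:00", tz = "UTC"))
      d <- summarize_days(s, thr)
      expect_equal(d$sedentary_minutes + d$light_minutes +
                     d$moderate_minutes + d$vigorous_minutes,
                   d$wear_minutes)
      expect_equal(d$mvpa_minutes, d$moderate_minutes + d$vigorous_minutes)
    }
  })
})

test_that("days split at calendar midnight", {
  s <- make_series(rep(1, 240),
                   start = as.POSIXct("2024-01-01 23:00:00", tz = "UTC"))
  d <- summarize_days(s, evenson_thresholds(30))
  expect_equal(nrow(d), 2)
  expect_equal(d$wear_minutes, c(60, 60))
  expect_equal(d$date, as.Date(c("2024-01-01", "2024-01-02")))
})
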