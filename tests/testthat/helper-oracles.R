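# Independent brute-force oracles and day builders used across tests.
# These deliberately avoid the package's own run-length / rank machinery:
# everything is explicit loops over epochs or full enumeration.

# maximal zero runs by explicit scan
brute_nonwear <- function(series, zero_run_minutes) {
  n <- length(series$counts)
  need_sec <- zero_run_minutes * 60
  out <- list()
  i <- 1
  while (i <= n) {
    if (series$counts[i] == 0) {
      j <- i
      while (j < n && series$counts[j + 1] == 0 &&
             abs(as.numeric(series$timestamps[j + 1] - series$timestamps[j],
                            units = "secs") - series$epoch_length) < 1e-6) {
        j <- j + 1
      }
      dur <- (j - i + 1) * series$epoch_length
      if (dur >= need_sec) {
        out[[length(out) + 1]] <- c(start = as.numeric(series$timestamps[i]),
                                    end = as.numeric(series$timestamps[j]) +
                                      series$epoch_length)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# all maximal runs over a label subset, by explicit scan
brute_runs <- function(classes, set) {
  runs <- list()
  i <- 1
  n <- length(classes)
  while (i <= n) {
    if (classes[i] %in% set) {
      j <- i
      while (j < n && classes[j + 1] %in% set) j <- j + 1
      runs[[length(runs) + 1]] <- c(start = i, len = j - i + 1)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  runs
}

# clause-by-clause stage verdict straight from the epoch labels
brute_stage_verdict <- function(stage, classes, epoch_len = 30,
                                baseline = NULL) {
  mins <- function(set) sum(classes %in% set) * epoch_len / 60
  wear <- length(classes) * epoch_len / 60
  mvpa <- mins(c("moderate", "vigorous"))
  lpa <- mins("light")
  run_mins <- function(set) {
    vapply(brute_runs(classes, set), function(r) r[["len"]] * epoch_len / 60,
           numeric(1))
  }
  if (stage == 1) {
    mvpa <= 0.025 * wear &&
      !any(run_mins(c("light", "moderate", "vigorous")) >= 5)
  } else if (stage == 2) {
    lpa <= baseline$lpa_minutes + 30 &&
      mvpa <= baseline$mvpa_minutes &&
      !any(run_mins(c("moderate", "vigorous")) >= 5)
  } else {
    long <- run_mins(c("moderate", "vigorous"))
    long <- long[long >= 5]
    mvpa <= baseline$mvpa_minutes + 60 &&
      length(long) <= 2 && all(long <= 15)
  }
}

# exact two-sided Mann-Whitney p by enumeration, counting discordant pairs
# directly (no ranks)
brute_mw_exact <- function(a, b) {
  u_of <- function(x, y) {
    u <- 0
    for (xi in x) for (yj in y) {
      u <- u + (xi > yj) + 0.5 * (xi == yj)
    }
    u
  }
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_obs <- u_of(a, b)
  us <- apply(utils::combn(n, na), 2, function(idx)
    u_of(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# a daily-summary-like record from an explicit label sequence
day_from_classes <- function(classes, epoch_len = 30) {
  mins <- function(set) sum(classes %in% set) * epoch_len / 60
  list(valid = TRUE,
       wear_minutes = length(classes) * epoch_len / 60,
       light_minutes = mins("light"),
       moderate_minutes = mins("moderate"),
       vigorous_minutes = mins("vigorous"),
       mvpa_minutes = mins(c("moderate", "vigorous")),
       epoch_classes = classes)
}

# random label sequence with realistic run structure (blocks of one class)
random_day_classes <- function(n_epochs, p = c(0.7, 0.2, 0.07, 0.03)) {
  out <- character(0)
  while (length(out) < n_epochs) {
    cls <- sample(c("sedentary", "light", "moderate", "vigorous"), 1,
                  prob = p)
    out <- c(out, rep(cls, sample(1:14, 1)))
  }
  out[seq_len(n_epochs)]
}

make_series <- function(counts, epoch_len = 30,
                        start = as.POSIXct("2024-01-01 00:00:00",
                                           tz = "UTC")) {
  epoch_series(start + (seq_along(counts) - 1) * epoch_len, counts,
               epoch_length = epoch_len)
}
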