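#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters governing epoch processing,
#' stage rules and labeling policy.  Every value can be overridden via a
#' YAML file (see [load_config()]) or by modifying the returned list.
#'
#' Key groups:
#' \describe{
#'   \item{thresholds}{Intensity cut points in counts per epoch at
#'     `epoch_length_s`.  Defaults are the child-calibrated
#'     counts-per-minute cut points (sedentary <= 100, light <= 2295,
#'     moderate <= 4011 cpm) scaled linearly to the 30-second epoch.}
#'   \item{nonwear}{`zero_run_min`: minimal run of consecutive zero-count
#'     epochs (minutes) flagged as algorithmic non-wear.}
#'   \item{valid_day}{Inclusive wear-time bounds (minutes) for a valid
#'     day; defaults 360 (6 h) and 1140 (19 h).}
#'   \item{policy}{Participant-level stage labeling: `mode` is
#'     `"any_day"` (adhered if at least one adherent valid day) or
#'     `"fraction"` with `fraction` (default 0.8, inclusive).}
#'   \item{baseline}{Fallback baseline daily light / moderate-to-vigorous
#'     minutes used when a participant has no valid days in the prior
#'     stage.}
#'   \item{selfreport}{`pcss_rule`: `"endpoint"` (final symptom score at
#'     or below the first) or `"monotone"` (never increasing);
#'     `horizon_days`: censoring horizon after injury.}
#' }
#'
#' @return Named nested list of parameters.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$policy$mode
default_config <- function() {
  list(
    epoch_length_s = 30,
    thresholds = list(sedentary_max = 50, light_max = 1147, moderate_max = 2005),
    nonwear = list(zero_run_min = 60),
    valid_day = list(min_min = 360, max_min = 1140),
    policy = list(mode = "any_day", fraction = 0.8),
    stage2 = list(mvpa_cap_mode = "baseline"),
    bouts = list(tolerance_epochs = 0),
    baseline = list(fallback = list(lpa = 120, mvpa = 15)),
    selfreport = list(pcss_rule = "endpoint", horizon_days = 180)
  )
}

# recursive merge: values in `override` win; unnamed/missing keep defaults
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]])
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file of overrides and merges it over [default_config()].
#' Unknown keys are an error so that typos cannot silently fall back to
#' defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Configuration list as from [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  override <- yaml::read_yaml(path)
  unknown <- setdiff(names(override), c(names(cfg), "simulation"))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  merge_config(cfg, override)
}
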