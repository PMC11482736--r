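INTENSITY_LEVELS <- c("sedentary", "light", "moderate", "vigorous")

#' Intensity cut points for epoch classification
#'
#' Constructs the three cut points that partition activity counts per
#' epoch into sedentary / light / moderate / vigorous.  Upper bounds are
#' inclusive: an epoch with counts equal to `sedentary_max` is sedentary.
#'
#' @param sedentary_max Maximal counts per epoch still classed sedentary.
#' @param light_max Maximal counts per epoch classed light.
#' @param moderate_max Maximal counts per epoch classed moderate; above
#'   this the epoch is vigorous.
#' @param epoch_length Epoch length in seconds the thresholds refer to.
#' @return An object of class `intensity_thresholds`.
#' @seealso [evenson_thresholds()] for the child-calibrated defaults.
#' @export
intensity_thresholds <- function(sedentary_max, light_max, moderate_max,
                                 epoch_length = 30) {
  stopifnot(length(sedentary_max) == 1, length(light_max) == 1,
            length(moderate_max) == 1)
  if (!(sedentary_max >= 0 && sedentary_max < light_max &&
        light_max < moderate_max)) {
    stop("thresholds must satisfy 0 <= sedentary_max < light_max < moderate_max",
         call. = FALSE)
  }
  structure(
    list(sedentary_max = sedentary_max, light_max = light_max,
         moderate_max = moderate_max, epoch_length = epoch_length),
    class = "intensity_thresholds"
  )
}

#' Child-calibrated cut points scaled to an epoch length
#'
#' The widely used child accelerometer cut points are defined per minute
#' of vertical-axis counts: sedentary <= 100, light 101--2295, moderate
#' 2296--4011, vigorous >= 4012 counts/min.  This helper scales them
#' linearly to the requested epoch length (floor of the scaled bound, so
#' 30-second epochs use 50 / 1147 / 2005).
#'
#' @param epoch_length Epoch length in seconds (default 30).
#' @return `intensity_thresholds` object.
#' @export
#' @examples
#' evenson_thresholds(30)
evenson_thresholds <- function(epoch_length = 30) {
  per_min <- c(sedentary = 100, light = 2295, moderate = 4011)
  scaled <- floor(per_min * epoch_length / 60)
  intensity_thresholds(scaled[["sedentary"]], scaled[["light"]],
                       scaled[["moderate"]], epoch_length = epoch_length)
}

#' @export
print.intensity_thresholds <- function(x, ...) {
  cat(sprintf(
    "Intensity thresholds (counts per %d-s epoch):\n  sedentary <= %d | light <= %d | moderate <= %d | vigorous > %d\n",
    x$epoch_length, x$sedentary_max, x$light_max, x$moderate_max,
    x$moderate_max))
  invisible(x)
}

#' Classify epoch counts into intensity classes
#'
#' Vectorised cut-point classification.  Bounds are inclusive upper
#' bounds for sedentary, light and moderate; anything above
#' `moderate_max` is vigorous.
#'
#' @param counts Non-negative integer vector of activity counts per epoch.
#' @param thresholds An [intensity_thresholds()] object.
#' @return Character vector over
#'   `c("sedentary", "light", "moderate", "vigorous")`.
#' @export
#' @examples
#' thr <- evenson_thresholds(30)
#' classify_epoch(c(0, 50, 51, 1148, 2006), thr)
classify_epoch <- function(counts, thresholds) {
  stopifnot(inherits(thresholds, "intensity_thresholds"))
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  breaks <- c(-Inf, thresholds$sedentary_max, thresholds$light_max,
              thresholds$moderate_max, Inf)
  as.character(cut(counts, breaks = breaks, labels = INTENSITY_LEVELS,
                   right = TRUE))
}
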