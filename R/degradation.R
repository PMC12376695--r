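# Degradation metrics from a bot's area time course.
#
# After dissolution from Matrigel, bots shrink and eventually disintegrate;
# the time course is summarized by eight area-derived metrics. "Untrackable"
# is operationalized as the area falling below a threshold (default 5% of
# the initial area) since segmentation loses the object around that point.

#' Eight degradation metrics from an area series
#'
#' The series is truncated immediately before the first frame whose area is
#' below \code{untrackable_below}; all metrics are computed on the retained
#' series. \code{changerate} is the maximum absolute second difference of
#' the areas (akin to a second derivative), or the signed maximum when
#' \code{signed_changerate = TRUE}.
#'
#' @param areas numeric vector of per-frame areas (pixel^2), nonnegative.
#' @param untrackable_below area threshold (pixel^2) below which the bot is
#'   considered untrackable; default 5\% of the first-frame area.
#' @param signed_changerate use the signed maximum second difference
#'   (default FALSE: maximum absolute value).
#' @return named numeric vector with \code{initial_area}, \code{fin_area},
#'   \code{change_in_area}, \code{percent_change}, \code{sd_diff},
#'   \code{mean_diff}, \code{time_to_disintegrate}, \code{changerate}.
#' @examples
#' degradation_features(c(100, 90, 80, 70, 60, 50), untrackable_below = 1)
#' @export
degradation_features <- function(areas, untrackable_below = NULL,
                                 signed_changerate = FALSE) {
  if (length(areas) == 0L) stop("degradation_features: empty area series")
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("degradation_features: areas must be finite and nonnegative")
  if (is.null(untrackable_below)) untrackable_below <- 0.05 * areas[1L]

  below <- which(areas < untrackable_below)
  keep <- if (length(below)) areas[seq_len(below[1L] - 1L)] else areas
  if (length(keep) == 0L)
    stop("degradation_features: bot untrackable from the first frame")

  d <- diff(keep)
  dd <- diff(d)
  changerate <- if (length(dd)) {
    if (signed_changerate) max(dd) else max(abs(dd))
  } else 0
  c(initial_area = keep[1L],
    fin_area = keep[length(keep)],
    change_in_area = keep[length(keep)] - keep[1L],
    percent_change = (keep[length(keep)] - keep[1L]) / keep[1L] * 100,
    sd_diff = if (length(d) >= 2L) sd(d) else 0,
    mean_diff = if (length(d) >= 1L) mean(d) else 0,
    time_to_disintegrate = length(keep),
    changerate = changerate)
}

#' Degradation features for a cohort of area series
#'
#' @param series named list of per-bot area vectors.
#' @param ... passed to \code{\link{degradation_features}}.
#' @return numeric matrix, bots x 8 metrics.
#' @export
degradation_feature_matrix <- function(series, ...) {
  feats <- t(vapply(series, function(a) degradation_features(a, ...),
                    numeric(8)))
  rownames(feats) <- names(series)
  feats
}
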