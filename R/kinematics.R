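# Trajectory kinematics and circular statistics for the eversion phase.
# A trajectory is the centroid series of one tracked bot, one row per frame
# at uniform spacing (hourly imaging in the source experiments), so speeds
# are in pixels per frame.

#' Circular variance of a set of angles
#'
#' One minus the mean resultant length \eqn{\bar R = |\sum_j e^{i\theta_j}|/n}.
#' Equals 0 when all angles coincide and approaches 1 when the unit vectors
#' balance out (e.g. two opposite headings).
#'
#' @param angles numeric vector of angles in radians; at least one value.
#' @return a value in \[0, 1\].
#' @export
circular_variance <- function(angles) {
  if (length(angles) == 0L) stop("circular_variance: empty angle vector")
  if (!all(is.finite(angles))) stop("circular_variance: non-finite angles")
  1 - mean_resultant_length(angles)
}

mean_resultant_length <- function(angles) {
  sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
}

#' Circular mean of angles (argument of the resultant vector)
#' @param angles numeric vector of angles in radians.
#' @return angle in (-pi, pi].
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0L) stop("circular_mean: empty angle vector")
  wrap_angle(atan2(mean(sin(angles)), mean(cos(angles))))
}

#' Circular median of angles
#'
#' The data angle minimizing the mean absolute circular deviation
#' (arc-length distance on the circle); ties resolved toward the smaller
#' angle value.
#'
#' @param angles numeric vector of angles in radians.
#' @return angle in radians (one of the input values).
#' @export
circular_median <- function(angles) {
  if (length(angles) == 0L) stop("circular_median: empty angle vector")
  cand <- sort(unique(angles))
  dev <- vapply(cand, function(a) {
    d <- abs(angles - a) %% (2 * pi)
    mean(pmin(d, 2 * pi - d))
  }, numeric(1))
  cand[which.min(dev)]  # which.min takes the first (smallest) on ties
}

#' Circular standard deviation, sqrt(-2 log Rbar)
#' @param angles numeric vector of angles in radians.
#' @return nonnegative value (0 when all angles coincide).
#' @export
circular_sd <- function(angles) {
  rbar <- mean_resultant_length(angles)
  # Rbar can exceed 1 by rounding for identical angles
  sqrt(-2 * log(min(rbar, 1)))
}

# wrap to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

as_trajectory <- function(t) {
  if (is.matrix(t)) t <- as.data.frame(t)
  if (!all(c("x", "y") %in% names(t)))
    stop("trajectory must have columns 'x' and 'y'")
  if (!is.null(t$frame) && is.unsorted(t$frame, strictly = TRUE))
    stop("trajectory frames must be strictly increasing")
  if (!all(is.finite(t$x)) || !all(is.finite(t$y)))
    stop("trajectory coordinates must be finite")
  t
}

#' Per-step kinematics of a trajectory
#'
#' For n points returns n-1 step distances, speeds (pixels/frame, frame
#' spacing fixed at 1) and headings, and n-2 signed angular speeds
#' (consecutive heading differences wrapped to (-pi, pi]). The heading of a
#' zero-length step is carried forward from the last moving step; leading
#' zero-length steps have no defined heading and are dropped from the
#' heading/angular-speed series.
#'
#' @param t trajectory: data frame (or matrix) with columns \code{x},
#'   \code{y} and optionally \code{frame}; at least 2 points.
#' @return list with numeric vectors \code{linear_distance},
#'   \code{linear_speed}, \code{heading}, \code{angular_speed}.
#' @examples
#' step_kinematics(data.frame(x = c(0, 1, 1), y = c(0, 0, 1)))
#' @export
step_kinematics <- function(t) {
  t <- as_trajectory(t)
  n <- nrow(t)
  if (n < 2L) stop("step_kinematics: need at least 2 points")
  dx <- diff(t$x)
  dy <- diff(t$y)
  d <- sqrt(dx^2 + dy^2)
  moving <- d > 0
  heading <- atan2(dy, dx)
  if (!any(moving)) {
    heading <- numeric(0)
  } else {
    first <- which(moving)[1L]
    # carry heading forward across zero-length steps
    for (i in seq_along(heading)) {
      if (i > first && !moving[i]) heading[i] <- heading[i - 1L]
    }
    heading <- heading[first:length(heading)]
  }
  omega <- if (length(heading) >= 2L) wrap_angle(diff(heading)) else numeric(0)
  list(linear_distance = d,
       linear_speed = d,  # frame spacing = 1
       heading = heading,
       angular_speed = omega)
}

#' Straightness index of a trajectory
#'
#' The mean resultant length of the step headings, i.e. 1 minus their
#' circular variance. Equals 1 for a perfectly straight monotone path and
#' 0 for an exact back-and-forth.
#'
#' @param t trajectory with at least 2 points (and at least one moving step).
#' @return value in \[0, 1\].
#' @export
straightness <- function(t) {
  k <- step_kinematics(t)
  if (length(k$heading) == 0L)
    stop("straightness: trajectory never moves, headings undefined")
  1 - circular_variance(k$heading)
}

#' Gyration index of a trajectory
#'
#' One minus the ratio of the circular variance of the signed angular speeds
#' to the circular variance of the angular speeds pooled with their additive
#' inverses; the pooled term accounts for the magnitude of the turning.
#' Equals 1 for constant-curvature (circular) motion. When the pooled
#' circular variance is below \code{eps} there is no net turning signal
#' (e.g. a straight line, all angular speeds 0) and the index is defined
#' as 0.
#'
#' @param t trajectory with at least 3 points.
#' @param eps degeneracy guard for the 0/0 case (default 1e-9).
#' @return value in \[0, 1\].
#' @export
gyration <- function(t, eps = 1e-9) {
  k <- step_kinematics(t)
  if (nrow(as_trajectory(t)) < 3L) stop("gyration: need at least 3 points")
  if (length(k$angular_speed) == 0L)
    stop("gyration: no angular speeds defined (trajectory never turns twice)")
  w <- k$angular_speed
  cv_pool <- circular_variance(c(w, -w))
  if (cv_pool < eps) return(0)
  val <- 1 - circular_variance(w) / cv_pool
  min(max(val, 0), 1)
}

#' 14-axis eversion feature vector
#'
#' Mean, median and standard deviation of the angular speed, linear
#' distance, heading and linear speed (12 values), plus the straightness
#' and gyration indices. Heading is summarized circularly (circular mean,
#' circular median, circular SD \eqn{\sqrt{-2\log\bar R}}); the signed
#' angular speed and the linear quantities use ordinary sample statistics
#' (SD with the n-1 denominator).
#'
#' @param t trajectory with at least 3 points.
#' @param circular_heading summarize heading with circular statistics
#'   (default TRUE); FALSE uses naive linear statistics of the angle values.
#' @return named numeric vector of length 14.
#' @export
eversion_features <- function(t, circular_heading = TRUE) {
  k <- step_kinematics(t)
  if (nrow(as_trajectory(t)) < 3L)
    stop("eversion_features: need at least 3 points")
  if (length(k$heading) == 0L)
    stop("eversion_features: trajectory never moves, headings undefined")
  h <- k$heading
  if (circular_heading) {
    hstats <- c(circular_mean(h), circular_median(h), circular_sd(h))
  } else {
    hstats <- c(mean(h), median(h), sd(h))
  }
  w <- k$angular_speed
  sd0 <- function(v) if (length(v) >= 2L) sd(v) else 0
  out <- c(
    mean_angular_speed   = mean(w),
    median_angular_speed = median(w),
    sd_angular_speed     = sd0(w),
    mean_linear_distance   = mean(k$linear_distance),
    median_linear_distance = median(k$linear_distance),
    sd_linear_distance     = sd0(k$linear_distance),
    mean_heading   = hstats[1],
    median_heading = hstats[2],
    sd_heading     = hstats[3],
    mean_linear_speed   = mean(k$linear_speed),
    median_linear_speed = median(k$linear_speed),
    sd_linear_speed     = sd0(k$linear_speed),
    straightness = straightness(t),
    gyration     = gyration(t)
  )
  out
}
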