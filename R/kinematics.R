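## Tail curvature, angle normalization, heading/eye angles, bout features.

#' Tail curvature from fitted tail points
#'
#' Converts an ordered tail polyline \eqn{P = [(x_0,y_0),...,(x_n,y_n)]}
#' (centroid first) into segment angles \eqn{\Theta = [\theta_1,...,\theta_n]}
#' normalized to the heading direction. The heading is
#' \eqn{\theta_h = -atan2(y_1 - y_0, x_1 - x_0)} (the sign flip converts the
#' y-down image angle to the counterclockwise-positive reporting convention);
#' every point is translated so the centroid sits at the origin and rotated
#' by \eqn{\theta_h}; the output angles are the bearings between successive
#' rotated points, so \eqn{\theta_1 = 0} by construction. The array is then
#' unwrapped (\code{\link{unwrapCurvature}}).
#'
#' @param points matrix with columns x, y; at least 3 rows.
#' @return numeric vector of length \code{nrow(points) - 1}.
#' @examples
#' P <- rbind(c(0, 0), c(0, 1), c(0, 2), c(1, 3))
#' calculateTailCurvature(P)  # 0, 0, -pi/4
#' @export
calculateTailCurvature <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("at least 3 tail points are required")
  d <- diff(points)
  if (any(rowSums(d^2) == 0))
    stop("coincident consecutive tail points: bearing undefined")
  thetaH <- -atan2(points[2, 2] - points[1, 2], points[2, 1] - points[1, 1])
  dx <- points[, 1] - points[1, 1]
  dy <- points[, 2] - points[1, 2]
  xs <- dx * cos(thetaH) - dy * sin(thetaH)
  ys <- dx * sin(thetaH) + dy * cos(thetaH)
  theta <- atan2(diff(ys), diff(xs))
  theta <- unwrapCurvature(theta)
  attr(theta, "thetaH") <- thetaH
  theta
}

#' Unwrap a curvature array
#'
#' Iterates along the array and offsets an angle by a multiple of 2*pi
#' whenever the absolute difference from the previous angle exceeds pi, so
#' successive angles are continuous across the -pi/pi wrap.
#'
#' @param theta numeric vector (non-empty).
#' @return unwrapped vector; idempotent.
#' @examples
#' unwrapCurvature(c(0, 3.04, -3.04))  # 0, 3.04, 3.04 + 2*pi - 2*pi ... 3.243
#' @export
unwrapCurvature <- function(theta) {
  if (length(theta) == 0) stop("empty curvature array")
  for (i in seq_along(theta)[-1]) {
    while (theta[i] - theta[i - 1] > pi) theta[i] <- theta[i] - 2 * pi
    while (theta[i] - theta[i - 1] < -pi) theta[i] <- theta[i] + 2 * pi
  }
  theta
}

#' Scalar tail angle
#'
#' The tail angle of a frame is the mean curvature of the last three tail
#' segments.
#'
#' @param theta curvature array, length >= 3.
#' @return mean of the final three entries, rad.
#' @export
tailAngle <- function(theta) {
  if (length(theta) < 3) stop("tail angle needs at least 3 segments")
  mean(tail(theta, 3))
}

#' Eye convergence angles relative to the heading
#'
#' For each eye, a point at distance \code{major} and angle \code{thetaM}
#' from the origin is rotated by the heading \eqn{\theta_h}; the rotated
#' bearing \eqn{\theta^* = atan2(y^*, x^*)} is the eye angle. Because a
#' region's major-axis orientation is only defined modulo pi, the angle is
#' offset by pi when it initially points against the heading, so each
#' reported eye angle lies within \code{(-pi/2, pi/2]} of the heading.
#'
#' @param eyes two-row data.frame from \code{\link{findEyeContours}} (needs
#'   \code{major} and \code{thetaM}, the image-convention major-axis
#'   orientation in [0, pi)), or any frame with those columns.
#' @param thetaH heading rotation angle, rad: the \eqn{\theta_h} produced by
#'   \code{\link{calculateTailCurvature}} (its sign convention already
#'   absorbs the image y-flip).
#' @return numeric vector of per-eye angles (rad, relative to heading, in
#'   the rotated heading-aligned frame; negate for the counterclockwise-
#'   positive reporting convention), named by side when available. Invariant
#'   to the major-axis length.
#' @export
calculateEyeAngles <- function(eyes, thetaH) {
  if (any(eyes$major <= 0)) stop("major axis length must be positive")
  thM <- eyes$thetaM
  x <- eyes$major * cos(thM)
  y <- eyes$major * sin(thM)
  xs <- x * cos(thetaH) - y * sin(thetaH)
  ys <- x * sin(thetaH) + y * cos(thetaH)
  th <- atan2(ys, xs)
  th[th > pi / 2] <- th[th > pi / 2] - pi
  th[th <= -pi / 2] <- th[th <= -pi / 2] + pi
  if (!is.null(eyes$side)) names(th) <- eyes$side
  th
}

#' Create a cumulative heading state
#'
#' @param initializeToZero if \code{TRUE}, the first reported sample is
#'   exactly 0 and later headings are relative to the first.
#' @return a \code{\linkS4class{HeadingState}}.
#' @export
headingState <- function(initializeToZero = FALSE) {
  new("HeadingState", initializeToZero = initializeToZero)
}

#' Update the cumulative heading
#'
#' The instantaneous heading is the angle from the body centroid to the
#' midpoint of the two eye centroids (eye variant) or from the first to the
#' second tail point (tail variant; this points caudally, consistent with
#' the \eqn{\theta_h} of \code{\link{calculateTailCurvature}}). Successive
#' instantaneous headings are unwrapped across frames so the cumulative
#' heading is unbounded.
#'
#' @param state a \code{\linkS4class{HeadingState}}.
#' @param centroid c(x, y), px (eye variant).
#' @param eyes two-row eye data.frame (x, y columns), or \code{NULL}.
#' @param tailPoints tail-point matrix (used when \code{eyes} is NULL).
#' @return list with the updated \code{state} and \code{heading} (rad,
#'   cumulative, counterclockwise-positive).
#' @export
calculateHeading <- function(state, centroid = NULL, eyes = NULL,
                             tailPoints = NULL) {
  if (!is.null(eyes)) {
    if (is.null(centroid)) stop("eye variant needs the centroid")
    mx <- mean(eyes$x); my <- mean(eyes$y)
    inst <- reportingAngle(mx - centroid[1], my - centroid[2])
  } else if (!is.null(tailPoints)) {
    inst <- reportingAngle(tailPoints[2, 1] - tailPoints[1, 1],
                           tailPoints[2, 2] - tailPoints[1, 2])
  } else stop("supply eyes + centroid, or tailPoints")
  if (is.na(state@cumulative)) {
    state@cumulative <- if (state@initializeToZero) 0 else inst
  } else {
    state@cumulative <- state@cumulative +
      wrapAngle(inst - state@lastInstantaneous)
  }
  state@lastInstantaneous <- inst
  list(state = state, heading = state@cumulative)
}

#' Clean a heading trace of tracking artifacts
#'
#' Scans the series with a 10 ms span; wherever the heading changes by more
#' than 180 degrees over that span, the implicated samples are removed (set
#' to \code{NA}) and all subsequent values are shifted so the first value
#' after the gap matches the value before it. Consecutive artifacts compose.
#'
#' @param series heading values, degrees.
#' @param fps sampling rate, Hz (> 0).
#' @return numeric vector with artifact samples \code{NA}; attribute
#'   \code{"shifts"} is a data.frame (index, shift) of the applied offsets
#'   (re-adding them over the removed spans reproduces the input).
#' @export
cleanHeadingTrace <- function(series, fps) {
  if (fps <= 0) stop("fps must be positive")
  w <- max(1L, as.integer(round(0.010 * fps)))
  x <- series
  n <- length(x)
  shifts <- list()
  i <- w + 1
  while (i <= n) {
    if (!is.na(x[i]) && !is.na(x[i - w]) && abs(x[i] - x[i - w]) > 180) {
      delta <- x[i - w] - x[i]
      gap <- (i - w + 1):i
      if (i < n) x[(i + 1):n] <- x[(i + 1):n] + delta
      x[gap] <- NA_real_
      shifts[[length(shifts) + 1]] <- data.frame(index = i, shift = delta)
      i <- i + 1
    } else i <- i + 1
  }
  attr(x, "shifts") <- if (length(shifts)) do.call(rbind, shifts)
    else data.frame(index = integer(0), shift = numeric(0))
  x
}

#' Segment bout intervals from per-frame flags
#'
#' Maximal runs of \code{TRUE} are extended by \code{round(0.015 * fps)}
#' frames on both sides (15 ms of padding), clipped to the record, and merged
#' where padded intervals overlap.
#'
#' @param flags logical vector of per-frame bout flags.
#' @param fps frames per second (> 0).
#' @return data.frame with 0-based \code{start} and \code{end} frame indices
#'   (inclusive); zero rows when no bout was flagged.
#' @examples
#' f <- rep(FALSE, 300); f[101:200] <- TRUE
#' segmentBouts(f, 332)  # 95 to 204 (5-frame pad)
#' @export
segmentBouts <- function(flags, fps) {
  if (fps <= 0) stop("fps must be positive")
  pad <- as.integer(round(0.015 * fps))
  r <- rle(as.logical(flags))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep)) return(data.frame(start = integer(0), end = integer(0)))
  s <- pmax(starts[keep] - pad, 1L) - 1L        # to 0-based
  e <- pmin(ends[keep] + pad, length(flags)) - 1L
  out <- data.frame(start = s[1], end = e[1])
  if (length(s) > 1) {
    for (k in 2:length(s)) {
      if (s[k] <= out$end[nrow(out)]) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], e[k])
      } else out <- rbind(out, data.frame(start = s[k], end = e[k]))
    }
  }
  out
}

#' Per-bout kinematic features
#'
#' Computes the four bout features used for behavioral clustering: mean of
#' the nonzero tail-beat-frequency samples, signed bout integral
#' (sum of the tail angle times 1/fps, rad s), SD of the tail angle, and the
#' signed maximum-magnitude tail angle. Absolute values of the integral and
#' max amplitude are taken only at clustering time.
#'
#' @param angles per-frame tail angle, rad.
#' @param tbf per-frame tail-beat frequency, Hz.
#' @param interval one-row data.frame (or list) with 0-based \code{start} and
#'   \code{end} inclusive frame indices, inside the record.
#' @param fps frames per second.
#' @return one-row data.frame: \code{meanTbf}, \code{integral},
#'   \code{sdTail}, \code{maxAmplitude}, \code{start}, \code{end}.
#' @export
computeBoutFeatures <- function(angles, tbf, interval, fps) {
  s <- interval$start; e <- interval$end
  if (is.null(s) || s < 0 || e >= length(angles) || e <= s)
    stop("bout interval must lie inside the record with end > start")
  idx <- (s:e) + 1L
  a <- angles[idx]
  f <- tbf[idx]
  data.frame(meanTbf = if (any(f > 0)) mean(f[f > 0]) else 0,
             integral = sum(a) / fps,
             sdTail = sd(a),
             maxAmplitude = a[which.max(abs(a))],
             start = s, end = e)
}
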