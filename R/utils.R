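## Small internal geometry/angle helpers shared across modules.

#' Wrap an angle into (-pi, pi]
#' @param a angle(s), radians.
#' @return wrapped angle(s).
#' @keywords internal
wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  # %% maps pi to -pi; keep the half-open interval (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Wrap degrees into [-180, 180)
#' @param d angle(s), degrees.
#' @return wrapped angle(s).
#' @keywords internal
wrapDegrees <- function(d) {
  ((d + 180) %% 360) - 180
}

## Unit vector in image coordinates (y down) for a reported ccw-positive angle.
reportingUnit <- function(a) c(cos(a), -sin(a))

## Reported ccw-positive angle of an image-space displacement (dx, dy).
reportingAngle <- function(dx, dy) -atan2(dy, dx)

## Circular absolute difference, radians.
circDiff <- function(a, b) abs(wrapAngle(a - b))

## Clamp numeric values.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Intensity lookup at integer 0-based pixel coordinates; NA outside.
pixelAt <- function(frame, x, y) {
  h <- nrow(frame); w <- ncol(frame)
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  out <- rep(NA_real_, length(x))
  if (any(ok)) out[ok] <- frame[cbind(y[ok] + 1, x[ok] + 1)]
  out
}

stopifnotFrame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("a frame must be a numeric matrix (nrow = height, ncol = width)")
  invisible(TRUE)
}

sameDims <- function(a, b) identical(dim(a), dim(b))
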