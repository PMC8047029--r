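## Virtual open-loop stimulus geometry: looming dot, heading-locked gratings,
## prey arc, and camera-display calibration.

#' Construct a looming-stimulus configuration
#'
#' @param lOverV angular half-size-to-speed ratio l/v, seconds (0.09 s =
#'   90 ms default).
#' @param staticDuration seconds the dot is shown at its initial size before
#'   expansion.
#' @param maxAngle truncation angle, degrees (the dot stops growing here).
#' @param expandToTruncation seconds from expansion onset to truncation;
#'   together with l/v this places the virtual collision time.
#' @param side \code{"left"} or \code{"right"}.
#' @param bearing degrees off the heading at which the dot is held.
#' @param distance mm from the centroid.
#' @return a list of class \code{"LoomingConfig"}.
#' @export
loomingConfig <- function(lOverV = 0.09, staticDuration = 10, maxAngle = 120,
                          expandToTruncation = 3,
                          side = c("left", "right"), bearing = 90,
                          distance = 10) {
  side <- match.arg(side)
  if (lOverV <= 0) stop("lOverV must be positive")
  if (maxAngle <= 0 || maxAngle >= 180) stop("maxAngle must be in (0, 180)")
  structure(list(lOverV = lOverV, staticDuration = staticDuration,
                 maxAngle = maxAngle, expandToTruncation = expandToTruncation,
                 side = side, bearing = bearing, distance = distance),
            class = "LoomingConfig")
}

#' Looming-dot angular size and world position
#'
#' The dot subtends the standard looming law
#' \eqn{\theta(t) = 2 \, atan\left(\frac{l/v}{t_c - t}\right)} where the
#' virtual collision time \eqn{t_c} is placed so the size reaches
#' \code{maxAngle} exactly \code{expandToTruncation} seconds after expansion
#' onset; it is clamped there afterwards. During the initial static period
#' the size is held at the expansion-onset value. The dot's world position is
#' continuously re-anchored at the configured bearing and distance relative
#' to the live fish pose (virtual open loop).
#'
#' @param t time within the trial, s (scalar or vector).
#' @param cfg a \code{\link{loomingConfig}}.
#' @param fishCentroid c(x, y) of the fish (any world units).
#' @param fishHeading heading, rad, counterclockwise-positive.
#' @return list: \code{angle} (deg, same length as t), \code{position}
#'   (matrix of dot centers, world coordinates, image-style y-down),
#'   \code{tc} (virtual collision time, s).
#' @export
loomingAngle <- function(t, cfg, fishCentroid = c(0, 0), fishHeading = 0) {
  halfMaxRad <- cfg$maxAngle / 2 * pi / 180
  tc <- cfg$staticDuration + cfg$expandToTruncation + cfg$lOverV / tan(halfMaxRad)
  law <- function(tt) 2 * atan(cfg$lOverV / (tc - tt)) * 180 / pi
  ang <- numeric(length(t))
  for (i in seq_along(t)) {
    tt <- max(t[i], cfg$staticDuration)      # static hold before expansion
    ang[i] <- if (tt >= tc - cfg$lOverV / tan(halfMaxRad)) cfg$maxAngle
      else law(tt)
  }
  ang <- pmin(ang, cfg$maxAngle)
  sgn <- if (cfg$side == "left") 1 else -1
  bear <- fishHeading + sgn * cfg$bearing * pi / 180
  pos <- matrix(rep(fishCentroid, each = length(t)), ncol = 2)
  pos[, 1] <- pos[, 1] + cfg$distance * cos(bear)
  pos[, 2] <- pos[, 2] - cfg$distance * sin(bear)
  list(angle = ang, position = pos, tc = tc)
}

#' Heading-locked optomotor grating state
#'
#' The grating drifts at \code{relativeDirection} degrees off the fish's
#' live heading, pivots about the fish centroid, and its phase advances at
#' the temporal frequency \code{speed / spatialPeriod}.
#'
#' @param fishCentroid c(x, y).
#' @param fishHeading heading, rad.
#' @param relativeDirection drift direction relative to heading, degrees
#'   (+90 or -90 in the standard assay).
#' @param t time, s.
#' @param speed drift speed (default 10 mm/s = 1 cm/s).
#' @param spatialPeriod grating spatial period (default 10 mm = 1 cm).
#' @return list: \code{orientation} (rad, drift direction, reporting
#'   convention), \code{pivot} (the centroid), \code{phase} (cycles in
#'   [0, 1)).
#' @export
omrGratingState <- function(fishCentroid, fishHeading, relativeDirection,
                            t = 0, speed = 10, spatialPeriod = 10) {
  list(orientation = wrapAngle(fishHeading + relativeDirection * pi / 180),
       pivot = fishCentroid,
       phase = (speed / spatialPeriod * t) %% 1)
}

#' Construct a prey-arc configuration
#'
#' @param arcHalfwidth degrees to each side of the heading (60 default, a
#'   120 degree arc).
#' @param radius mm from the centroid (5 default).
#' @param peakSpeed deg/s at the front of the arc (100 default).
#' @param mode \code{"sweeping"} (sinusoidal sweep) or
#'   \code{"fixed_lateral"} (dot pinned at one lateral extreme).
#' @param fixedSide \code{"left"} or \code{"right"} for fixed_lateral mode.
#' @param dotDiameter mm (< 1 in the standard assay; metadata only).
#' @return a list of class \code{"PreyArcConfig"}.
#' @export
preyArcConfig <- function(arcHalfwidth = 60, radius = 5, peakSpeed = 100,
                          mode = c("sweeping", "fixed_lateral"),
                          fixedSide = c("left", "right"), dotDiameter = 0.8) {
  if (peakSpeed <= 0 || radius <= 0) stop("peakSpeed and radius must be > 0")
  structure(list(arcHalfwidth = arcHalfwidth, radius = radius,
                 peakSpeed = peakSpeed, mode = match.arg(mode),
                 fixedSide = match.arg(fixedSide), dotDiameter = dotDiameter),
            class = "PreyArcConfig")
}

#' Virtual prey position along the arc
#'
#' In sweeping mode the arc angle is \eqn{\phi(t) = A \sin(\omega t)} with
#' \eqn{A} the arc halfwidth and \eqn{\omega = peakSpeed / A}, so the
#' angular speed peaks at \code{peakSpeed} directly in front of the fish
#' (\eqn{\phi = 0}) and falls to 0 at the arc ends. Fixed-lateral mode pins
#' the dot at one extreme. The dot sits at the configured radius along
#' bearing \eqn{\phi} off the live heading; the reported yaw is \eqn{\phi}
#' (degrees, positive = fish's left).
#'
#' @param t time, s (scalar or vector).
#' @param cfg a \code{\link{preyArcConfig}}.
#' @param fishCentroid c(x, y) world position.
#' @param fishHeading heading, rad.
#' @return list: \code{yaw} (deg), \code{position} (matrix, y-down world
#'   coordinates), \code{arcSpeed} (deg/s, signed).
#' @export
preyPosition <- function(t, cfg, fishCentroid = c(0, 0), fishHeading = 0) {
  A <- cfg$arcHalfwidth
  if (cfg$mode == "sweeping") {
    om <- cfg$peakSpeed / A
    yaw <- A * sin(om * t)
    speed <- cfg$peakSpeed * cos(om * t)
  } else {
    yaw <- rep(if (cfg$fixedSide == "left") A else -A, length(t))
    speed <- rep(0, length(t))
  }
  bear <- fishHeading + yaw * pi / 180
  pos <- cbind(fishCentroid[1] + cfg$radius * cos(bear),
               fishCentroid[2] - cfg$radius * sin(bear))
  list(yaw = yaw, position = pos, arcSpeed = speed)
}

#' Camera-to-display calibration
#'
#' Builds the affine map taking the camera-space rectangle onto the
#' display-space rectangle (corner correspondence). Every stimulus position
#' is pushed through this map before output.
#'
#' @param cameraRect,displayRect rectangles c(x, y, width, height), px.
#' @return list of class \code{"CalibrationParameters"} with the forward
#'   2x3 affine matrix \code{A} and its inverse \code{Ainv}.
#' @examples
#' cal <- calibrate(c(0, 0, 100, 100), c(10, 20, 200, 200))
#' mapPoint(cal, c(50, 50))  # (110, 120)
#' @export
calibrate <- function(cameraRect, displayRect) {
  if (cameraRect[3] <= 0 || cameraRect[4] <= 0 ||
      displayRect[3] <= 0 || displayRect[4] <= 0)
    stop("rectangles must be non-degenerate")
  sx <- displayRect[3] / cameraRect[3]
  sy <- displayRect[4] / cameraRect[4]
  tx <- displayRect[1] - sx * cameraRect[1]
  ty <- displayRect[2] - sy * cameraRect[2]
  A <- rbind(c(sx, 0, tx), c(0, sy, ty))
  Ainv <- rbind(c(1 / sx, 0, -tx / sx), c(0, 1 / sy, -ty / sy))
  structure(list(A = A, Ainv = Ainv), class = "CalibrationParameters")
}

#' Apply (or invert) a calibration map
#'
#' @param cal a \code{\link{calibrate}} result.
#' @param p point c(x, y) or matrix with columns x, y.
#' @param inverse map display back to camera space.
#' @return mapped point(s), same shape as the input.
#' @export
mapPoint <- function(cal, p, inverse = FALSE) {
  M <- if (inverse) cal$Ainv else cal$A
  if (is.matrix(p)) {
    t(apply(p, 1, function(q) as.numeric(M %*% c(q, 1))))
  } else as.numeric(M %*% c(p, 1))
}
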