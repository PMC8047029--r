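## Iterative point-to-point contrast-based tail-point fitting.

.circleCache <- new.env(parent = emptyenv())

#' Precompute rasterized circle points
#'
#' Integer points whose rounded Euclidean distance from the origin equals
#' \code{radius}, sorted by polar angle (image convention, y down), each with
#' its angle cached. Results are memoized per radius.
#'
#' @param radius circle radius in px (>= 1).
#' @return data.frame with columns \code{x}, \code{y} (integer offsets) and
#'   \code{angle} (image-space polar angle in (-pi, pi], strictly
#'   increasing).
#' @examples
#' nrow(precomputeCirclePoints(1))  # the 4-neighborhood ring
#' @export
precomputeCirclePoints <- function(radius) {
  if (radius < 1) stop("radius must be >= 1")
  key <- format(radius)
  if (!is.null(.circleCache[[key]])) return(.circleCache[[key]])
  r <- ceiling(radius)
  g <- expand.grid(x = -r:r, y = -r:r)
  keep <- round(sqrt(g$x^2 + g$y^2)) == round(radius)
  g <- g[keep, , drop = FALSE]
  g$angle <- atan2(g$y, g$x)
  g <- g[order(g$angle), , drop = FALSE]
  rownames(g) <- NULL
  .circleCache[[key]] <- g
  g
}

## Candidate points of an arc of total angular length `range` centered at
## image angle `center`, ordered by circular offset from the arc start.
arcPoints <- function(circle, center, range) {
  off <- wrapAngle(circle$angle - center)
  keep <- abs(off) <= range / 2
  sub <- circle[keep, , drop = FALSE]
  sub <- sub[order(off[keep]), , drop = FALSE]
  sub
}

## Score an arc of candidate pixel positions (0-based, integer) on a frame,
## returning the index of the chosen point per the configured method.
## Candidates outside the frame are dropped by the caller.
chooseArcPoint <- function(vals, xs, ys, method, polarity) {
  if (polarity == "darkest") {
    ext <- min(vals); ref <- max(vals)
  } else {
    ext <- max(vals); ref <- min(vals)
  }
  if (method == "pixel_search") {
    return(which(vals == ext)[1])  # tie: first in arc order
  }
  w <- abs(vals - ref)
  if (sum(w) == 0) return(1L)  # uniform arc: degenerate, first point
  if (method == "weighted_median") {
    cw <- cumsum(w)
    return(which(cw >= sum(w) / 2)[1])
  }
  # center_of_mass: arc point nearest the intensity-difference center of mass
  cx <- sum(w * xs) / sum(w); cy <- sum(w * ys) / sum(w)
  d <- (xs - cx)^2 + (ys - cy)^2
  which(d == min(d))[1]
}

#' Fit tail points by iterative contrast search
#'
#' Starting from the centroid, the first tail point is found on a circle of
#' radius \code{distTailBase}: a full-circle extremum search when the heading
#' is unset (negative \code{headingDirection}), or the circle point at the
#' angle opposite the provided heading. Each subsequent point is searched on
#' an arc (length \code{rangeTailPointAngles}) of the \code{distTailPoints}
#' circle whose midpoint continues the direction of the previous two points;
#' the point is scored by the configured contrast method. X/Y offsets are
#' applied last.
#'
#' @param frame numeric matrix (raw frame with a dark fish, or a
#'   background-subtracted frame with \code{pixelPolarity = "lightest"}).
#' @param centroid c(x, y) seed (0-based px) or a \code{zebCentroid}; a
#'   no-detection centroid propagates (returns \code{NULL}).
#' @param cfg a \code{\linkS4class{TailFitConfig}}.
#' @return matrix of \code{numTailSegments + 2} points (columns x, y),
#'   ordered from the centroid to the tail tip, or \code{NULL} if the
#'   centroid was a no-detection. Arcs that leave the frame are clamped to
#'   in-frame candidates with a warning.
#' @examples
#' r <- renderFishFrame(fishPose(c(60, 60), heading = pi), c(120, 120))
#' cfg <- tailFitConfig(numTailSegments = 7)
#' pts <- calculateTailPoints(255 - r$frame, c(60, 60),
#'                            cfg)  # bright fish: polarity "lightest"
#' @export
calculateTailPoints <- function(frame, centroid, cfg) {
  stopifnotFrame(frame)
  if (inherits(centroid, "zebCentroid")) {
    if (!centroid$detected) return(NULL)
    centroid <- c(centroid$x, centroid$y)
  }
  nPts <- cfg@numTailSegments + 2L
  pts <- matrix(NA_real_, nPts, 2, dimnames = list(NULL, c("x", "y")))
  pts[1, ] <- centroid
  c1 <- precomputeCirclePoints(cfg@distTailBase)
  c2 <- precomputeCirclePoints(cfg@distTailPoints)
  base <- round(centroid)

  pickOnCircle <- function(circle, origin, center = NULL, range = 2 * pi) {
    sub <- if (is.null(center)) circle else arcPoints(circle, center, range)
    xs <- origin[1] + sub$x; ys <- origin[2] + sub$y
    vals <- pixelAt(frame, xs, ys)
    ok <- !is.na(vals)
    if (!all(ok)) {
      warning("search arc clamped to frame bounds")
      xs <- xs[ok]; ys <- ys[ok]; vals <- vals[ok]
    }
    if (length(vals) == 0) return(NULL)
    i <- chooseArcPoint(vals, xs, ys, cfg@method, cfg@pixelPolarity)
    c(xs[i], ys[i])
  }

  if (cfg@headingDirection < 0) {
    p1 <- pickOnCircle(c1, base)
  } else {
    # point at the circle angle opposite the heading (image convention:
    # reporting angle a maps to image angle -a)
    target <- wrapAngle(-(cfg@headingDirection + pi))
    i <- which.min(circDiff(c1$angle, target))
    p1 <- base + c(c1$x[i], c1$y[i])
  }
  if (is.null(p1)) stop("first tail point search found no in-frame candidates")
  pts[2, ] <- p1

  for (k in 3:nPts) {
    prev <- pts[k - 1, ]; prev2 <- pts[k - 2, ]
    dir <- atan2(prev[2] - prev2[2], prev[1] - prev2[1])  # image angle
    p <- pickOnCircle(c2, round(prev), center = dir,
                      range = cfg@rangeTailPointAngles)
    if (is.null(p)) {
      warning("tail search arc fully outside frame; truncating")
      pts[k, ] <- prev
    } else pts[k, ] <- p
  }
  pts[, 1] <- pts[, 1] + cfg@offsetX
  pts[, 2] <- pts[, 2] + cfg@offsetY
  pts
}

#' Construct a tail-fit configuration
#'
#' @param distTailBase,distTailPoints search radii, px.
#' @param rangeTailPointAngles arc length, rad.
#' @param numTailSegments tail segments; output has this plus 2 points.
#' @param method \code{"pixel_search"}, \code{"weighted_median"} or
#'   \code{"center_of_mass"}.
#' @param pixelPolarity \code{"darkest"} or \code{"lightest"}.
#' @param headingDirection known heading (rad); negative = unset
#'   (full-circle search).
#' @param offsetX,offsetY output coordinate offsets, px.
#' @return a \code{\linkS4class{TailFitConfig}}.
#' @export
tailFitConfig <- function(distTailBase = 12, distTailPoints = 6,
                          rangeTailPointAngles = 2 * pi / 3,
                          numTailSegments = 7,
                          method = c("pixel_search", "weighted_median",
                                     "center_of_mass"),
                          pixelPolarity = c("darkest", "lightest"),
                          headingDirection = -1, offsetX = 0, offsetY = 0) {
  new("TailFitConfig", distTailBase = distTailBase,
      distTailPoints = distTailPoints,
      rangeTailPointAngles = rangeTailPointAngles,
      numTailSegments = as.integer(numTailSegments),
      method = match.arg(method), pixelPolarity = match.arg(pixelPolarity),
      headingDirection = headingDirection,
      offsetX = offsetX, offsetY = offsetY)
}

setMethod("show", "TailFitConfig", function(object) {
  cat("TailFitConfig:", object@numTailSegments, "segments,",
      object@method, "/", object@pixelPolarity, "\n")
  cat("  radii:", object@distTailBase, "(base) /", object@distTailPoints,
      "(points) px; arc", round(object@rangeTailPointAngles, 3), "rad\n")
})
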