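## Centroid extraction and eye-region extraction from thresholded frames.

## Threshold a frame into a logical mask. "binary": pixel > value;
## "inverted": pixel <= value (mirrors an inverted binary threshold).
thresholdMask <- function(frame, value, type = c("binary", "inverted")) {
  type <- match.arg(type)
  if (type == "binary") frame > value else frame <= value
}

## Label connected components of a logical mask [y, x]; returns an integer
## matrix in the same layout (EBImage works in x-major layout, so transpose
## through it).
labelRegions <- function(mask) {
  lab <- EBImage::bwlabel(t(mask * 1))
  t(EBImage::imageData(lab))
}

## Per-region pixel statistics: area, centroid (0-based), second moments.
regionStats <- function(labels) {
  idx <- which(labels > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(label = integer(0), area = numeric(0), x = numeric(0),
                      y = numeric(0), mu20 = numeric(0), mu02 = numeric(0),
                      mu11 = numeric(0)))
  lab <- labels[idx]
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  ux <- tapply(x, lab, mean); uy <- tapply(y, lab, mean)
  area <- tapply(x, lab, length)
  mu20 <- tapply(seq_along(lab), lab, function(i) mean((x[i] - mean(x[i]))^2))
  mu02 <- tapply(seq_along(lab), lab, function(i) mean((y[i] - mean(y[i]))^2))
  mu11 <- tapply(seq_along(lab), lab, function(i)
    mean((x[i] - mean(x[i])) * (y[i] - mean(y[i]))))
  data.frame(label = as.integer(names(area)), area = as.numeric(area),
             x = as.numeric(ux), y = as.numeric(uy),
             mu20 = as.numeric(mu20), mu02 = as.numeric(mu02),
             mu11 = as.numeric(mu11))
}

noDetection <- function(method) {
  structure(list(detected = FALSE, x = NA_real_, y = NA_real_,
                 area = NA_real_, method = method), class = "zebCentroid")
}

#' @export
print.zebCentroid <- function(x, ...) {
  if (x$detected)
    cat(sprintf("centroid (%.2f, %.2f), area %s [%s]\n", x$x, x$y,
                ifelse(is.na(x$area), "-", format(x$area)), x$method))
  else cat("no detection [", x$method, "]\n", sep = "")
  invisible(x)
}

#' Centroid of a thresholded frame
#'
#' Finds the animal's centroid either from the raw image moments of the whole
#' thresholded mask or as the centroid of the largest connected region whose
#' area falls inside \code{[minArea, maxArea]} (regions outside the range are
#' discarded).
#'
#' @param frame numeric matrix (a background-subtracted frame, typically).
#' @param thresholdValue intensity threshold.
#' @param thresholdType \code{"binary"} (pixel > value is foreground) or
#'   \code{"inverted"} (pixel <= value).
#' @param method \code{"largest_binary_region"} (default; robust to noise) or
#'   \code{"raw_image_moments"}.
#' @param minArea,maxArea allowed region area (px^2), largest-region method
#'   only.
#' @param prevCentroid optional previous-frame centroid c(x, y) used only to
#'   break exact area ties (nearest region wins; otherwise topmost-leftmost).
#' @return a \code{zebCentroid}: list with \code{detected}, \code{x},
#'   \code{y}, \code{area}, \code{method}. An empty mask or no region in the
#'   allowed area range gives \code{detected = FALSE} (never a silent (0,0)).
#' @examples
#' f <- matrix(0, 40, 40); f[20:23, 10:13] <- 255
#' calculateCentroid(f, 128)
#' @export
calculateCentroid <- function(frame, thresholdValue,
                              thresholdType = c("binary", "inverted"),
                              method = c("largest_binary_region",
                                         "raw_image_moments"),
                              minArea = 0, maxArea = Inf,
                              prevCentroid = NULL) {
  stopifnotFrame(frame)
  method <- match.arg(method)
  mask <- thresholdMask(frame, thresholdValue, thresholdType)
  if (method == "raw_image_moments") {
    idx <- which(mask, arr.ind = TRUE)
    if (nrow(idx) == 0) return(noDetection(method))
    return(structure(list(detected = TRUE, x = mean(idx[, 2] - 1),
                          y = mean(idx[, 1] - 1), area = nrow(idx),
                          method = method), class = "zebCentroid"))
  }
  st <- regionStats(labelRegions(mask))
  st <- st[st$area >= minArea & st$area <= maxArea, , drop = FALSE]
  if (nrow(st) == 0) return(noDetection(method))
  best <- st[st$area == max(st$area), , drop = FALSE]
  if (nrow(best) > 1) {
    if (!is.null(prevCentroid)) {
      d <- (best$x - prevCentroid[1])^2 + (best$y - prevCentroid[2])^2
      best <- best[which.min(d), , drop = FALSE]
    } else {
      best <- best[order(best$y, best$x)[1], , drop = FALSE]
    }
  }
  structure(list(detected = TRUE, x = best$x, y = best$y, area = best$area,
                 method = method), class = "zebCentroid")
}

#' All candidate centroids in an area range
#'
#' Multi-animal variant of \code{\link{calculateCentroid}}: returns the
#' centroid of every connected region whose area lies in the allowed range,
#' ordered by decreasing area.
#'
#' @inheritParams calculateCentroid
#' @return data.frame with columns \code{x}, \code{y}, \code{area} (possibly
#'   zero rows).
#' @export
detectCentroids <- function(frame, thresholdValue,
                            thresholdType = c("binary", "inverted"),
                            minArea = 0, maxArea = Inf) {
  stopifnotFrame(frame)
  mask <- thresholdMask(frame, thresholdValue, thresholdType)
  st <- regionStats(labelRegions(mask))
  st <- st[st$area >= minArea & st$area <= maxArea, , drop = FALSE]
  st <- st[order(-st$area), c("x", "y", "area"), drop = FALSE]
  rownames(st) <- NULL
  st
}

#' Extract the left and right eye regions
#'
#' Labels the connected regions of a binary mask, discards regions whose area
#' lies outside \code{[minArea, maxArea]}, whose distance from the fish
#' centroid lies outside \code{[minDistance, maxDistance]}, or whose bearing
#' relative to the heading falls outside \code{+/- angleRange/2}; the two
#' survivors are ordered by signed bearing so the \emph{left} eye (positive,
#' counterclockwise bearing off the heading) comes first.
#'
#' @param mask logical matrix (eye-level threshold of a frame), or a numeric
#'   frame together with \code{thresholdValue}.
#' @param centroid c(x, y) fish centroid (e.g. the first fitted tail point
#'   seed), 0-based px.
#' @param heading heading, rad, counterclockwise-positive.
#' @param minArea,maxArea allowed region area, px^2.
#' @param minDistance,maxDistance allowed centroid-to-region distance, px.
#' @param angleRange full width (rad) of the search cone centered on the
#'   heading.
#' @param fitEllipses if \code{TRUE} (default) report moment-based ellipse
#'   parameters (major-axis length and orientation) for each eye.
#' @param thresholdValue optional; when \code{mask} is numeric, foreground is
#'   \code{mask > thresholdValue}.
#' @return list with \code{detected}; when \code{TRUE}, \code{eyes} is a
#'   two-row data.frame (left then right) with centroid, area, signed
#'   bearing (rad), major-axis length \code{major} and orientation
#'   \code{thetaM} (rad, in [0, pi), image convention, as a region's raw
#'   second moments define it). When a number of
#'   regions other than two survives, \code{detected = FALSE} and
#'   \code{nRegions} carries the survivor count.
#' @export
findEyeContours <- function(mask, centroid, heading,
                            minArea = 2, maxArea = 200,
                            minDistance = 0, maxDistance = 30,
                            angleRange = pi, fitEllipses = TRUE,
                            thresholdValue = NULL) {
  if (is.numeric(mask) && !is.logical(mask)) {
    if (is.null(thresholdValue))
      stop("numeric input requires thresholdValue")
    mask <- mask > thresholdValue
  }
  st <- regionStats(labelRegions(mask))
  st$dist <- sqrt((st$x - centroid[1])^2 + (st$y - centroid[2])^2)
  st$bearing <- wrapAngle(reportingAngle(st$x - centroid[1],
                                         st$y - centroid[2]) - heading)
  keep <- st$area >= minArea & st$area <= maxArea &
    st$dist >= minDistance & st$dist <= maxDistance &
    abs(st$bearing) <= angleRange / 2
  st <- st[keep, , drop = FALSE]
  if (nrow(st) != 2)
    return(list(detected = FALSE, nRegions = nrow(st)))
  st <- st[order(-st$bearing), , drop = FALSE]  # left (positive) first
  st$side <- c("left", "right")
  if (fitEllipses) {
    lam <- with(st, {
      tr <- mu20 + mu02
      d <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
      (tr + d) / 2
    })
    st$major <- 4 * sqrt(pmax(lam, 0))
    ## image-convention (y down) major-axis orientation, [0, pi); this is the
    ## convention calculateEyeAngles() expects
    st$thetaM <- (0.5 * atan2(2 * st$mu11, st$mu20 - st$mu02)) %% pi
  }
  rownames(st) <- NULL
  cols <- c("side", "x", "y", "area", "dist", "bearing",
            if (fitEllipses) c("major", "thetaM"))
  list(detected = TRUE, eyes = st[, cols])
}
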