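## Frame I/O, configuration, and pipeline orchestration.

#' Read a frame sequence from an image directory
#'
#' Reads a numbered PNG image sequence into a list of 8-bit grayscale
#' matrices; color inputs are converted by Rec. 709 luminance. Frames are
#' delivered in lexicographic filename order with 0-based indices; re-reading
#' a directory is bit-identical.
#'
#' @param source directory containing \code{.png} frames.
#' @return list of numeric matrices (0--255), names = source filenames.
#' @export
readFrames <- function(source) {
  if (!dir.exists(source)) stop("no such frame directory: ", source)
  files <- sort(list.files(source, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG frames found in ", source)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) {
      img <- 0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3]
    }
    img * 255
  })
  names(frames) <- basename(files)
  frames
}

#' Write a background image as PNG
#'
#' @param model an initialized \code{\linkS4class{BackgroundModel}}.
#' @param path output PNG path.
#' @return invisibly, the path.
#' @export
writeBackground <- function(model, path) {
  img <- backgroundImage(model)
  if (length(img) == 0) stop("background model is uninitialized")
  png::writePNG(clamp(img, 0, 255) / 255, path)
  invisible(path)
}

#' Read a pipeline configuration
#'
#' Loads a YAML configuration and merges it over the package defaults.
#' Keys mirror the tracking property names in snake_case
#' (\code{pixel_search}, \code{noise_threshold}, \code{threshold_value},
#' \code{threshold_type}, \code{min_area}, \code{max_area},
#' \code{dist_tail_base}, \code{dist_tail_points},
#' \code{range_tail_point_angles}, \code{num_tail_segments},
#' \code{tail_point_method}, \code{pixel_polarity}, \code{heading_direction},
#' \code{offset_x}, \code{offset_y}, \code{bout_threshold},
#' \code{peak_threshold}, \code{frame_window}, \code{frame_rate},
#' \code{n_fish}, \code{px_per_mm}, \code{seed}).
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return named list of configuration values.
#' @export
readConfig <- function(path = NULL) {
  defaults <- list(
    pixel_search = "lightest", noise_threshold = 0,
    threshold_value = 60, threshold_type = "binary",
    min_area = 10, max_area = 1e5,
    dist_tail_base = 12, dist_tail_points = 6,
    range_tail_point_angles = 2 * pi / 3, num_tail_segments = 7,
    tail_point_method = "pixel_search", pixel_polarity = "lightest",
    heading_direction = -1, offset_x = 0, offset_y = 0,
    bout_threshold = 0.1, peak_threshold = 0.05,
    frame_window = NA, frame_rate = 332,
    n_fish = 1, px_per_mm = 10, seed = 1)
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  if (length(bad <- setdiff(names(user), names(defaults))))
    warning("unknown config keys ignored: ", paste(bad, collapse = ", "))
  utils::modifyList(defaults, user[intersect(names(user), names(defaults))])
}

cfgTailFit <- function(cfg) {
  tailFitConfig(distTailBase = cfg$dist_tail_base,
                distTailPoints = cfg$dist_tail_points,
                rangeTailPointAngles = cfg$range_tail_point_angles,
                numTailSegments = cfg$num_tail_segments,
                method = cfg$tail_point_method,
                pixelPolarity = cfg$pixel_polarity,
                headingDirection = cfg$heading_direction,
                offsetX = cfg$offset_x, offsetY = cfg$offset_y)
}

#' Track a single-fish recording
#'
#' Runs the full single-animal pipeline over a frame sequence: a first pass
#' builds the running-extremum background, then per frame the stages run in
#' order — background subtraction, centroid calculation, tail-point fitting,
#' curvature, tail angle, online bout detection, heading. Per-frame failures
#' produce a row of \code{NA}s plus a warning; the run always completes.
#'
#' @param frames list of frames (see \code{\link{readFrames}}), or a single
#'   frame matrix repeated input.
#' @param cfg configuration list from \code{\link{readConfig}}.
#' @return list of data.frames: \code{tailPoints} (frame, x0, y0, ...),
#'   \code{kinematics} (frame, tailAngle, bout, tbf, amplitude, heading,
#'   plus theta1..thetaN curvature columns).
#' @export
trackVideo <- function(frames, cfg = readConfig()) {
  bg <- backgroundModel(cfg$pixel_search, cfg$noise_threshold)
  for (f in frames) {
    bg <- tryCatch(updateBackground(bg, f), error = function(e) bg)
  }
  tcfg <- cfgTailFit(cfg)
  fw <- if (is.na(cfg$frame_window)) round(0.15 * cfg$frame_rate)
    else cfg$frame_window
  det <- boutDetector(cfg$bout_threshold, cfg$peak_threshold,
                      frameRate = cfg$frame_rate, frameWindow = fw)
  hs <- headingState()
  nSeg <- cfg$num_tail_segments
  nPts <- nSeg + 2
  ptCols <- paste0(c("x", "y"), rep(0:(nPts - 1), each = 2))
  thCols <- paste0("theta", 1:(nPts - 1))
  rows <- vector("list", length(frames))
  kin <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fi <- i - 1L
    res <- tryCatch({
      fg <- subtractBackground(frames[[i]], bg)
      cen <- calculateCentroid(fg, cfg$threshold_value, cfg$threshold_type,
                               minArea = cfg$min_area, maxArea = cfg$max_area)
      pts <- calculateTailPoints(fg, cen, tcfg)
      if (is.null(pts)) stop("no centroid detected")
      theta <- calculateTailCurvature(pts)
      ta <- tailAngle(theta)
      db <- detectTailBeat(det, ta)
      det <- db$detector
      hh <- calculateHeading(hs, tailPoints = pts)
      hs <- hh$state
      list(pts = pts, theta = theta, ta = ta, k = db$kinematics,
           heading = hh$heading)
    }, error = function(e) {
      warning(sprintf("frame %d: %s", fi, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) {
      rows[[i]] <- as.data.frame(as.list(setNames(
        c(fi, rep(NA_real_, 2 * nPts)), c("frame", ptCols))))
      kin[[i]] <- as.data.frame(as.list(setNames(
        c(fi, rep(NA_real_, nPts + 3)),
        c("frame", "tailAngle", "tbf", "amplitude", thCols, "heading"))))
      kin[[i]]$bout <- NA
    } else {
      rows[[i]] <- as.data.frame(as.list(setNames(
        c(fi, as.vector(t(res$pts))), c("frame", ptCols))))
      k <- as.data.frame(as.list(setNames(
        c(fi, res$ta, res$k$frequency, res$k$amplitude,
          as.numeric(res$theta), res$heading),
        c("frame", "tailAngle", "tbf", "amplitude", thCols, "heading"))))
      k$bout <- res$k$bout
      kin[[i]] <- k
    }
  }
  list(tailPoints = do.call(rbind, rows), kinematics = do.call(rbind, kin))
}

#' Track identities in a multi-fish recording
#'
#' First pass builds the background; second pass extracts all candidate
#' centroids per frame (area-filtered) and chains the minimum-distance
#' identity assignment across frames, flagging contacts at merged centroids.
#'
#' @param frames list of frames.
#' @param cfg configuration list; \code{n_fish} sets the expected identity
#'   count (taken from the first frame when fewer are found there).
#' @return list: \code{identities} (see \code{\link{trackIdentities}}),
#'   \code{discardMask} (per-frame logical), \code{accuracy} (a
#'   \code{\link{percentAccuracy}} report over identity-frames).
#' @export
trackMultiple <- function(frames, cfg = readConfig()) {
  bg <- backgroundModel(cfg$pixel_search, cfg$noise_threshold)
  for (f in frames) {
    bg <- tryCatch(updateBackground(bg, f), error = function(e) bg)
  }
  cens <- lapply(frames, function(f) {
    fg <- subtractBackground(f, bg)
    detectCentroids(fg, cfg$threshold_value, cfg$threshold_type,
                    minArea = cfg$min_area, maxArea = cfg$max_area)
  })
  ids <- trackIdentities(cens)
  mask <- contactDiscardMask(ids)
  acc <- percentAccuracy(nrow(ids), sum(ids$contact))
  list(identities = ids, discardMask = mask, accuracy = acc)
}

#' Write tracking results to CSV files
#'
#' Comma-separated, header row, UTF-8; angles in radians, frame indices and
#' pixel coordinates 0-based.
#'
#' @param results output of \code{\link{trackVideo}} or
#'   \code{\link{trackMultiple}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
writeTrackingCsvs <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(results)) {
    if (!is.data.frame(results[[nm]])) next
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(results[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
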