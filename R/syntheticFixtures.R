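## Synthetic ground-truthed fixtures: rendered fish frames, swim traces,
## paramecia-like prey paths, and labeled bout-feature sets.

## Evaluate expr under a temporary RNG seed, restoring global RNG state.
## All stochastic generators in the package take an explicit seed; none
## touch global random state persistently.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

#' Construct a synthetic fish pose
#'
#' @param centroid length-2 pixel coordinates (0-based) of the body centroid.
#' @param heading heading, rad, counterclockwise-positive (0 = +x).
#' @param segmentAngles inter-segment tail angles, rad, relative to the caudal
#'   direction; all zeros give a straight tail opposite the heading.
#' @param ... further slots of \code{\linkS4class{FishPose}}
#'   (\code{bodyIntensity}, \code{tailWidth}, ...).
#' @return a \code{\linkS4class{FishPose}}.
#' @examples
#' p <- fishPose(c(80, 80), heading = 0, segmentAngles = numeric(7))
#' @export
fishPose <- function(centroid = c(80, 80), heading = 0,
                     segmentAngles = numeric(7), ...) {
  new("FishPose", centroid = as.numeric(centroid), heading = heading,
      segmentAngles = as.numeric(segmentAngles), ...)
}

#' Draw a random fish pose
#'
#' Samples a centroid near the frame center, a uniform heading, and a smooth
#' random tail curvature, suitable for tracking-recovery experiments.
#'
#' @param seed integer seed (explicit; global RNG state is untouched).
#' @param frameSize c(width, height) in px.
#' @param numSegments tail segments.
#' @param maxCurve SD (rad) of the per-segment angle increments; increments
#'   are clipped to \code{[-0.35, 0.35]} so the polyline never kinks faster
#'   than the tracker's arc search can follow.
#' @param ... passed to \code{\link{fishPose}}.
#' @return a \code{\linkS4class{FishPose}}.
#' @export
randomFishPose <- function(seed, frameSize = c(160, 160), numSegments = 7,
                           maxCurve = 0.18, ...) {
  withSeed(seed, {
    ctr <- frameSize / 2 + runif(2, -12, 12)
    heading <- runif(1, -pi, pi)
    seg <- clamp(rnorm(numSegments, 0, maxCurve), -0.35, 0.35)
    fishPose(centroid = ctr, heading = heading, segmentAngles = seg, ...)
  })
}

#' Ground-truth tail polyline of a pose
#'
#' @param pose a \code{\linkS4class{FishPose}}.
#' @return (numSegments + 2) x 2 matrix of 0-based pixel coordinates ordered
#'   centroid to tail tip; spacing is \code{distTailBase} for the first gap
#'   and \code{distTailPoints} thereafter.
#' @export
poseTailPoints <- function(pose) {
  n <- length(pose@segmentAngles)
  pts <- matrix(NA_real_, n + 2, 2)
  pts[1, ] <- pose@centroid
  caudal <- pose@heading + pi
  dirs <- caudal + cumsum(c(0, pose@segmentAngles))[seq_len(n + 1)]
  pts[2, ] <- pts[1, ] + pose@distTailBase * reportingUnit(dirs[1])
  for (k in seq_len(n)) {
    pts[k + 2, ] <- pts[k + 1, ] + pose@distTailPoints * reportingUnit(dirs[k + 1])
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Eye ellipse placement of a pose
#'
#' @param pose a \code{\linkS4class{FishPose}}.
#' @return data.frame with one row per eye (left first): center, semi-axes,
#'   orientation (rad, reporting convention) and signed bearing off heading.
#' @export
poseEyes <- function(pose) {
  bearing <- c(pose@eyeBearing, -pose@eyeBearing)  # left then right
  ang <- pose@heading + bearing
  ctr <- t(vapply(ang, function(a)
    pose@centroid + pose@eyeDistance * reportingUnit(a), numeric(2)))
  data.frame(side = c("left", "right"), x = ctr[, 1], y = ctr[, 2],
             a = pose@eyeAxes[1], b = pose@eyeAxes[2],
             orientation = ang, bearing = bearing,
             stringsAsFactors = FALSE)
}

## Soft-edged filled-ellipse weight field on a pixel grid.
## X, Y: matrices of 0-based pixel coordinates; orientation is a reporting
## angle (ccw-positive); edgeSigma in px.
ellipseField <- function(X, Y, center, a, b, orientation, edgeSigma = 0.6) {
  co <- cos(orientation); si <- -sin(orientation)  # image-space axis vector
  dx <- X - center[1]; dy <- Y - center[2]
  xr <- dx * co + dy * si
  yr <- -dx * si + dy * co
  r <- sqrt((xr / a)^2 + (yr / b)^2)
  out <- exp(-(pmax(r - 1, 0) * b)^2 / (2 * edgeSigma^2))
  out[r <= 1] <- 1
  out
}

## Gaussian-stroke weight field through a polyline.
strokeField <- function(X, Y, pts, sigma) {
  s <- matrix(0, nrow(X), ncol(X))
  for (k in seq_len(nrow(pts) - 1)) {
    p <- pts[k, ]; q <- pts[k + 1, ]
    v <- q - p; L2 <- sum(v^2)
    dx <- X - p[1]; dy <- Y - p[2]
    tt <- if (L2 > 0) clamp((dx * v[1] + dy * v[2]) / L2, 0, 1) else 0
    d2 <- (dx - tt * v[1])^2 + (dy - tt * v[2])^2
    s <- pmax(s, exp(-d2 / (2 * sigma^2)))
  }
  s
}

#' Render a synthetic fish frame with ground truth
#'
#' Draws an anti-aliased fish on a flat background: a soft-edged body ellipse
#' centered on the centroid (containing the two brighter eye ellipses, as in
#' real larvae where the eyes are the darkest features inside the body), and
#' a smooth Gaussian-cross-section tail stroke through the ground-truth
#' polyline. The relative contrasts (eyes > body > tail) allow a single
#' intensity threshold to isolate the body for centroid detection and a
#' higher threshold to isolate the eyes.
#'
#' @param pose a \code{\linkS4class{FishPose}}.
#' @param size c(width, height) of the frame, px.
#' @return list with \code{frame} (numeric matrix, 0--255) and \code{truth}
#'   (list: \code{points} tail polyline, \code{centroid}, \code{heading},
#'   \code{eyes} from \code{\link{poseEyes}}).
#' @examples
#' r <- renderFishFrame(fishPose(c(60, 60), heading = pi / 4), c(120, 120))
#' dim(r$frame)
#' @export
setMethod("renderFishFrame", signature("FishPose", "numeric"),
  function(pose, size) {
    w <- size[1]; h <- size[2]
    pts <- poseTailPoints(pose)
    bad <- which(pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1)
    if (length(bad))
      stop(sprintf("tail exits frame bounds at segment %d", bad[1] - 1))
    X <- matrix(rep(0:(w - 1), each = h), h, w)
    Y <- matrix(rep(0:(h - 1), times = w), h, w)
    sigma <- pose@tailWidth / 2.355  # tailWidth ~ FWHM of the stroke
    sTail <- 0.55 * strokeField(X, Y, pts, sigma)
    sBody <- 0.80 * ellipseField(X, Y, pose@centroid, pose@bodyAxes[1],
                                 pose@bodyAxes[2], pose@heading)
    eyes <- poseEyes(pose)
    sEye <- matrix(0, h, w)
    for (i in 1:2) {
      sEye <- pmax(sEye, ellipseField(X, Y, c(eyes$x[i], eyes$y[i]),
                                      eyes$a[i], eyes$b[i],
                                      eyes$orientation[i], edgeSigma = 0.4))
    }
    s <- pmax(sTail, sBody, sEye)
    frame <- pose@backgroundIntensity +
      s * (pose@bodyIntensity - pose@backgroundIntensity)
    frame <- clamp(frame, 0, 255)
    list(frame = frame,
         truth = list(points = pts, centroid = pose@centroid,
                      heading = pose@heading, eyes = eyes))
  })

#' Generate a ground-truthed tail-angle swim trace
#'
#' Within each bout the angle is
#' \code{amplitude * sin(2*pi*f*(t - onset)) + bias}; outside bouts it is 0.
#' Gaussian noise of SD \code{noiseSd} is added everywhere.
#'
#' @param fps frames per second (> 0).
#' @param duration seconds.
#' @param bouts list of bouts, each a list with \code{onset} (s),
#'   \code{duration} (s), \code{freq} (Hz, < fps/2), \code{amplitude} (rad)
#'   and optional \code{bias} (rad, default 0). Bouts must not overlap.
#' @param noiseSd additive Gaussian noise SD, rad.
#' @param seed explicit integer seed (only used when \code{noiseSd > 0}).
#' @return data.frame with columns \code{frame} (0-based), \code{t},
#'   \code{angle}, \code{bout} (ground-truth flag) and \code{frequency}
#'   (ground-truth instantaneous frequency, 0 outside bouts); attribute
#'   \code{"peakTimes"} holds, per bout, the times of the signed amplitude
#'   extrema.
#' @examples
#' tr <- generateSwimTrace(332, 1, list(list(onset = .2, duration = .5,
#'                                           freq = 20, amplitude = .5)))
#' sum(tr$bout) / 332  # ~0.5 s
#' @export
generateSwimTrace <- function(fps, duration, bouts = list(), noiseSd = 0,
                              seed = NULL) {
  if (fps <= 0) stop("fps must be positive")
  n <- round(fps * duration)
  t <- (0:(n - 1)) / fps
  angle <- numeric(n)
  flag <- logical(n)
  freq <- numeric(n)
  if (length(bouts)) {
    on <- vapply(bouts, `[[`, numeric(1), "onset")
    du <- vapply(bouts, `[[`, numeric(1), "duration")
    o <- order(on)
    if (any(on[o][-1] < (on + du)[o][-length(o)]))
      stop("bouts must not overlap")
  }
  peaks <- vector("list", length(bouts))
  for (i in seq_along(bouts)) {
    b <- bouts[[i]]
    if (b$freq >= fps / 2)
      stop(sprintf("beat frequency %.1f Hz aliases at %.0f fps", b$freq, fps))
    bias <- b$bias %||% 0
    idx <- which(t >= b$onset & t < b$onset + b$duration)
    angle[idx] <- b$amplitude * sin(2 * pi * b$freq * (t[idx] - b$onset)) + bias
    flag[idx] <- TRUE
    freq[idx] <- b$freq
    k <- 0:floor(2 * b$freq * b$duration)
    pk <- b$onset + (2 * k + 1) / (4 * b$freq)
    peaks[[i]] <- pk[pk < b$onset + b$duration]
  }
  if (noiseSd > 0) {
    angle <- angle + withSeed(seed, rnorm(n, 0, noiseSd))
  }
  out <- data.frame(frame = 0:(n - 1), t = t, angle = angle, bout = flag,
                    frequency = freq)
  attr(out, "peakTimes") <- peaks
  out
}

#' Generate paramecia-like virtual prey trajectories
#'
#' Each prey alternates straight runs, brief pauses, and reorientations; the
#' linear velocity, run distance, pause length, angular velocity and new
#' orientation are randomized per episode. Paths reflect at the arena walls.
#'
#' @param n number of prey (>= 1).
#' @param arena c(width, height), mm.
#' @param duration seconds.
#' @param fps sampling rate of the output positions, Hz.
#' @param seed explicit integer seed.
#' @param speedRange linear run speed range, mm/s.
#' @param runRange run distance range, mm.
#' @param pauseRange pause duration range, s.
#' @param turnRange reorientation angular speed range, deg/s.
#' @param dotDiameter dot diameter metadata, mm (carried on the output).
#' @return data.frame: \code{prey} (1..n), \code{frame}, \code{t}, \code{x},
#'   \code{y}, \code{orientation} (rad, reporting convention), \code{state}
#'   (run/pause/turn). Attribute \code{"dotDiameter"}.
#' @export
generatePreyPaths <- function(n, arena = c(60, 60), duration = 60, fps = 60,
                              seed = 1, speedRange = c(0.5, 2),
                              runRange = c(2, 10), pauseRange = c(0.2, 1),
                              turnRange = c(45, 180), dotDiameter = 1) {
  if (n < 1) stop("n must be >= 1")
  nf <- round(duration * fps)
  dt <- 1 / fps
  withSeed(seed, {
    res <- vector("list", n)
    for (p in seq_len(n)) {
      x <- runif(1, 0.1, 0.9) * arena[1]
      y <- runif(1, 0.1, 0.9) * arena[2]
      ori <- runif(1, -pi, pi)
      state <- "run"
      speed <- runif(1, speedRange[1], speedRange[2])
      remain <- runif(1, runRange[1], runRange[2]) / speed
      turnRate <- 0
      X <- Y <- O <- numeric(nf)
      S <- character(nf)
      for (f in seq_len(nf)) {
        if (state == "run") {
          x <- x + speed * cos(ori) * dt
          y <- y - speed * sin(ori) * dt
          # reflect at walls
          if (x < 0) { x <- -x; ori <- wrapAngle(pi - ori) }
          if (x > arena[1]) { x <- 2 * arena[1] - x; ori <- wrapAngle(pi - ori) }
          if (y < 0) { y <- -y; ori <- wrapAngle(-ori) }
          if (y > arena[2]) { y <- 2 * arena[2] - y; ori <- wrapAngle(-ori) }
        } else if (state == "turn") {
          ori <- wrapAngle(ori + turnRate * dt)
        }
        X[f] <- x; Y[f] <- y; O[f] <- ori; S[f] <- state
        remain <- remain - dt
        if (remain <= 0) {
          state <- switch(state, run = "pause", pause = "turn", turn = "run")
          if (state == "run") {
            speed <- runif(1, speedRange[1], speedRange[2])
            remain <- runif(1, runRange[1], runRange[2]) / speed
          } else if (state == "pause") {
            remain <- runif(1, pauseRange[1], pauseRange[2])
          } else {
            sweep <- runif(1, -pi, pi)
            rate <- runif(1, turnRange[1], turnRange[2]) * pi / 180
            if (rate <= 0) {            # degenerate: no reorientation
              turnRate <- 0; remain <- 0
            } else {
              turnRate <- sign(sweep) * rate
              remain <- abs(sweep) / rate
            }
          }
        }
      }
      res[[p]] <- data.frame(prey = p, frame = 0:(nf - 1), t = (0:(nf - 1)) * dt,
                             x = X, y = Y, orientation = O, state = S,
                             stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    attr(out, "dotDiameter") <- dotDiameter
    out
  })
}

#' Generate a labeled Gaussian bout-feature mixture
#'
#' Draws per-class Gaussian samples in the four-dimensional bout feature
#' space (mean tail-beat frequency, |bout integral|, bout SD, |max
#' amplitude|), with labels retained, as a planted-truth fixture for
#' clustering.
#'
#' @param nPerClass samples per class (recycled across classes).
#' @param classParams list (length >= 2) of lists with \code{mean} and
#'   \code{sd}, each length 4, ordered (meanTbf, integral, sdTail,
#'   maxAmplitude). SDs must be positive.
#' @param seed explicit integer seed.
#' @return data.frame: \code{meanTbf}, \code{integral}, \code{sdTail},
#'   \code{maxAmplitude}, \code{label}.
#' @export
generateBoutFeatureClusters <- function(nPerClass, classParams, seed = 1) {
  if (length(classParams) < 2) stop("at least 2 classes are required")
  nPerClass <- rep_len(nPerClass, length(classParams))
  for (cp in classParams) {
    if (length(cp$mean) != 4 || length(cp$sd) != 4)
      stop("each class needs length-4 mean and sd")
    if (any(cp$sd <= 0)) stop("class SDs must be positive")
  }
  withSeed(seed, {
    rows <- lapply(seq_along(classParams), function(k) {
      cp <- classParams[[k]]
      m <- matrix(rnorm(nPerClass[k] * 4), ncol = 4)
      m <- sweep(sweep(m, 2, cp$sd, `*`), 2, cp$mean, `+`)
      data.frame(meanTbf = m[, 1], integral = m[, 2], sdTail = m[, 3],
                 maxAmplitude = m[, 4], label = k)
    })
    do.call(rbind, rows)
  })
}

#' Save a rendered frame sequence plus ground truth to disk
#'
#' Writes zero-padded PNG files and a ground-truth CSV (frame, tail point
#' coordinates, heading).
#'
#' @param frames list of rendered results from \code{\link{renderFishFrame}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
saveFrameSequence <- function(frames, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    png::writePNG(frames[[i]]$frame / 255,
                  file.path(dir, sprintf("frame_%06d.png", i - 1)))
    pts <- frames[[i]]$truth$points
    row <- c(frame = i - 1, heading = frames[[i]]$truth$heading,
             setNames(as.vector(t(pts)),
                      paste0(c("x", "y"), rep(0:(nrow(pts) - 1), each = 2))))
    truth[[i]] <- as.data.frame(as.list(row))
  }
  write.csv(do.call(rbind, truth), file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
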