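## One- and two-dimensional closed-loop optomotor feedback computations.

#' Construct a one-dimensional feedback configuration
#'
#' @param baselineVelocity baseline grating velocity, mm/s.
#' @param gain reafference gain.
#' @param frameRate acquisition rate, Hz.
#' @param windowMs integration window, ms.
#' @param decayMs exponential decay time constant, ms.
#' @param vigorScale mm/s per raw vigor unit (see
#'   \code{\link{calibrateVigorScale}}).
#' @param signedVigor keep the sign of the tail-angle derivative (default
#'   \code{FALSE}: magnitude, so a beat in either direction slows the
#'   grating).
#' @return a \code{\linkS4class{FeedbackConfig1D}}.
#' @export
feedbackConfig1D <- function(baselineVelocity = 10, gain = 1,
                             frameRate = 332, windowMs = 15, decayMs = 9,
                             vigorScale = NA_real_, signedVigor = FALSE) {
  new("FeedbackConfig1D", baselineVelocity = baselineVelocity, gain = gain,
      windowMs = windowMs, decayMs = decayMs, frameRate = frameRate,
      vigorScale = vigorScale, signedVigor = signedVigor)
}

## Window length in frames and exponential weights of the vigor kernel.
vigorKernel <- function(cfg) {
  n <- max(1L, as.integer(round(cfg@windowMs / 1000 * cfg@frameRate)))
  dtMs <- 1000 / cfg@frameRate
  list(n = n, weights = exp(-(0:(n - 1)) * dtMs / cfg@decayMs))
}

#' Swim vigor from a tail-angle history
#'
#' The vigor at frame t is the mean over the last \code{windowMs} of the
#' tail-angle derivative, each sample exponentially discounted by its age
#' with time constant \code{decayMs} (simulating burst-and-glide
#' acceleration), multiplied by the bout instance: vigor is exactly zero
#' outside detected bouts. By default the magnitude of the derivative is
#' used.
#'
#' @param angles per-frame tail angle, rad.
#' @param boutFlags per-frame logical bout instance.
#' @param cfg a \code{\linkS4class{FeedbackConfig1D}}.
#' @return per-frame raw vigor (rad/s units, before \code{vigorScale}).
#' @export
swimVigor <- function(angles, boutFlags, cfg) {
  k <- vigorKernel(cfg)
  if (length(angles) < k$n) stop("angle history shorter than the window")
  deriv <- c(0, diff(angles)) * cfg@frameRate
  if (!cfg@signedVigor) deriv <- abs(deriv)
  v <- as.numeric(stats::filter(deriv, k$weights, method = "convolution",
                                sides = 1)) / k$n
  v[is.na(v)] <- 0
  v * as.numeric(boutFlags)
}

#' Calibrate the vigor scale
#'
#' Solves, once per (frameRate, window, decay), for the scale that maps the
#' steady-state vigor of a sustained reference bout (20 Hz, unit amplitude
#' sine) to a 20 mm/s forward translation at gain 1. The steady state is
#' measured as the mean vigor over the final second of a 2 s reference bout
#' (an integer number of beat cycles).
#'
#' @param cfg a \code{\linkS4class{FeedbackConfig1D}}.
#' @param refFrequency reference tail-beat frequency, Hz.
#' @param refAmplitude reference amplitude, rad.
#' @param targetVelocity translation the reference bout must map to at
#'   gain 1, mm/s.
#' @return the configuration with \code{vigorScale} filled in.
#' @export
calibrateVigorScale <- function(cfg, refFrequency = 20, refAmplitude = 1,
                                targetVelocity = 20) {
  fps <- cfg@frameRate
  n <- as.integer(round(2 * fps))
  t <- (0:(n - 1)) / fps
  ref <- refAmplitude * sin(2 * pi * refFrequency * t)
  v <- swimVigor(ref, rep(TRUE, n), cfg)
  steady <- mean(v[t >= 1])
  if (steady <= 0) stop("reference bout produced no vigor")
  cfg@vigorScale <- targetVelocity / steady
  cfg
}

#' One-dimensional closed-loop stimulus velocity
#'
#' \eqn{V_S = V_B - gain \cdot vigorScale \cdot vigor}: the baseline velocity
#' minus the (calibrated, gain-scaled) swim vigor. With the standard
#' calibration and a baseline of 10 mm/s, a sustained 20 Hz bout yields
#' -10, 0 and -20 mm/s at gains 1.0, 0.5 and 1.5.
#'
#' @param vigor raw vigor (from \code{\link{swimVigor}}).
#' @param cfg a calibrated \code{\linkS4class{FeedbackConfig1D}}.
#' @return stimulus velocity, mm/s (same length as \code{vigor}).
#' @export
stimulusVelocity1D <- function(vigor, cfg) {
  if (is.na(cfg@vigorScale))
    stop("configuration is not calibrated; run calibrateVigorScale() first")
  cfg@baselineVelocity - cfg@gain * cfg@vigorScale * vigor
}

#' Construct a two-dimensional feedback configuration
#'
#' @param baselineVelocity baseline velocity, mm/s.
#' @param gain gain factor.
#' @param frameRate acquisition rate, Hz.
#' @param boxcarMs moving-average window on the tail-beat frequency, ms.
#' @param segments tail segments averaged for the curvature term.
#' @return a \code{\linkS4class{FeedbackConfig2D}}.
#' @export
feedbackConfig2D <- function(baselineVelocity = 10, gain = 1, frameRate = 332,
                             boxcarMs = 15, segments = 1) {
  new("FeedbackConfig2D", baselineVelocity = baselineVelocity, gain = gain,
      boxcarMs = boxcarMs, frameRate = frameRate,
      segments = as.integer(segments))
}

#' Two-dimensional closed-loop stimulus velocity
#'
#' \eqn{V_S = V_B - boxcar(F) \cdot gain \cdot (1 - |\theta| / 90)}: the
#' boxcar-averaged tail-beat frequency drives the stimulus, scaled by an
#' orientation factor that is 1 when the stimulus is aligned with the
#' heading (\eqn{\theta = 0}), 0 at \eqn{|\theta| = 90} degrees, and -1 at
#' 180 degrees (swimming then speeds the stimulus up). \eqn{\theta} lives on
#' [-180, 180); the factor is continuous inside the interval but jumps at
#' the wrap point itself (\eqn{\theta = 180} is represented as -180, where
#' the factor is again -1, so the jump is in \eqn{\theta}, not the factor).
#'
#' @param tbf per-frame tail-beat frequency, Hz.
#' @param thetaDeg stimulus orientation(s) relative to heading, degrees in
#'   [-180, 180) (wrapped if not).
#' @param cfg a \code{\linkS4class{FeedbackConfig2D}}.
#' @return stimulus velocity, mm/s, per frame.
#' @export
stimulusVelocity2D <- function(tbf, thetaDeg, cfg) {
  n <- max(1L, as.integer(round(cfg@boxcarMs / 1000 * cfg@frameRate)))
  box <- as.numeric(stats::filter(tbf, rep(1 / n, n), sides = 1))
  box[is.na(box)] <- 0
  theta <- wrapDegrees(thetaDeg)
  cfg@baselineVelocity - box * cfg@gain * (1 - abs(theta) / 90)
}

#' Stimulus angular velocity from tail curvature
#'
#' \eqn{V_\theta = \overline{TC} / (t - t_0)}: the mean tail curvature over
#' the configured segments, weighted by the inverse of the time since bout
#' onset, so early-bout curvature turns the stimulus more than the same
#' curvature later in the bout.
#'
#' @param meanCurvature mean tail curvature across segments at time t, rad.
#' @param t current time, s (> t0).
#' @param t0 bout onset time, s.
#' @return angular velocity, rad/s.
#' @export
stimulusAngularVelocity <- function(meanCurvature, t, t0) {
  if (any(t <= t0)) stop("t must be greater than the bout onset t0")
  meanCurvature / (t - t0)
}

#' Gain schedule over trials
#'
#' 54 trials in three identical blocks of 18: three trials each of medium
#' (1.0), low (0.5), high (1.5) gain, then medium, high, low.
#'
#' @param trialIndex 0-based trial index in [0, 53].
#' @return gain value in \{0.5, 1.0, 1.5\}.
#' @examples
#' gainSchedule(0)   # 1.0
#' gainSchedule(3)   # 0.5
#' gainSchedule(12)  # 1.5
#' @export
gainSchedule <- function(trialIndex) {
  if (any(trialIndex < 0 | trialIndex > 53))
    stop("trialIndex must lie in [0, 53]")
  pattern <- rep(c(1.0, 0.5, 1.5, 1.0, 1.5, 0.5), each = 3)
  pattern[(trialIndex %% 18) + 1]
}

#' Run a one-dimensional closed-loop trial
#'
#' Applies the feedback equation frame by frame during the motion period and
#' holds the stimulus at 0 mm/s outside it. Bout instances come from the
#' online detector unless supplied.
#'
#' @param angles per-frame tail angle, rad, covering the whole trial.
#' @param cfg calibrated \code{\linkS4class{FeedbackConfig1D}}.
#' @param motionStart,motionDuration motion period, s (default: a 10 s trial
#'   starting at t = 0).
#' @param boutFlags optional per-frame logical; when \code{NULL} a
#'   \code{\link{boutDetector}} with default thresholds is run on the trace.
#' @return data.frame: \code{frame}, \code{t}, \code{angle}, \code{bout},
#'   \code{vigor} (raw), \code{Vs} (mm/s); exactly one row per input frame.
#' @export
runTrial1D <- function(angles, cfg, motionStart = 0, motionDuration = 10,
                       boutFlags = NULL) {
  n <- length(angles)
  t <- (0:(n - 1)) / cfg@frameRate
  if (is.null(boutFlags)) {
    det <- boutDetector(frameRate = cfg@frameRate)
    boutFlags <- detectTailBeats(det, angles)$bout
  }
  vigor <- swimVigor(angles, boutFlags, cfg)
  vs <- stimulusVelocity1D(vigor, cfg)
  motion <- t >= motionStart & t < motionStart + motionDuration
  vs[!motion] <- 0
  data.frame(frame = 0:(n - 1), t = t, angle = angles,
             bout = as.logical(boutFlags), vigor = vigor, Vs = vs)
}

setMethod("show", "FeedbackConfig1D", function(object) {
  cat("FeedbackConfig1D: V_B =", object@baselineVelocity, "mm/s, gain",
      object@gain, "\n  window", object@windowMs, "ms, decay",
      object@decayMs, "ms @", object@frameRate, "Hz; vigorScale",
      if (is.na(object@vigorScale)) "<uncalibrated>"
      else format(object@vigorScale, digits = 4), "\n")
})

setMethod("show", "FeedbackConfig2D", function(object) {
  cat("FeedbackConfig2D: V_B =", object@baselineVelocity, "mm/s, gain",
      object@gain, ", boxcar", object@boxcarMs, "ms @", object@frameRate,
      "Hz\n")
})
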