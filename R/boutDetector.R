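## Online bout and tail-beat-frequency detection (streaming).

#' Create an online bout detector
#'
#' @param boutThreshold excursion (rad) from the running window extremum that
#'   starts a bout.
#' @param peakThreshold reversal (rad) that confirms an inflection peak.
#' @param frameRate acquisition rate, Hz.
#' @param frameWindow running-window length in frames; also how many quiet
#'   frames end a bout. Default \code{round(0.15 * frameRate)} (150 ms).
#' @param cycleMode \code{"full"} (default): tail-beat frequency from the
#'   spacing of successive same-direction peaks, i.e. one full oscillation
#'   cycle, so a 20 Hz sine reads 20 Hz. \code{"half"}: from successive
#'   alternating peaks, doubled.
#' @return a \code{\linkS4class{BoutDetector}}.
#' @examples
#' det <- boutDetector(0.1, 0.05, frameRate = 332)
#' @export
boutDetector <- function(boutThreshold = 0.1, peakThreshold = 0.05,
                         frameRate = 332,
                         frameWindow = round(0.15 * frameRate),
                         cycleMode = c("full", "half")) {
  new("BoutDetector", boutThreshold = boutThreshold,
      peakThreshold = peakThreshold, frameWindow = as.integer(frameWindow),
      frameRate = frameRate, cycleMode = match.arg(cycleMode))
}

#' Feed one tail angle to the bout detector
#'
#' Compares the incoming angle to the running minimum and maximum over the
#' last \code{frameWindow} frames. A bout starts when the excursion from the
#' opposite extremum exceeds \code{boutThreshold}. Inside a bout the detector
#' alternates direction, confirming a peak whenever the angle retreats from
#' the current extremum by more than \code{peakThreshold}; the peak amplitude
#' is that extremum (signed), and each confirmed peak re-arms the expiry
#' counter. After two peaks in the same direction the frequency is the frame
#' rate divided by the frames of one full cycle. If the counter passes
#' \code{frameWindow} without a re-trigger, the bout ends and amplitude and
#' frequency are reset to 0.
#'
#' @param detector a \code{\linkS4class{BoutDetector}}.
#' @param angle current tail angle, rad (must be finite).
#' @return list with the updated \code{detector} and \code{kinematics}: a
#'   list \code{(frequency, amplitude, bout)}.
#' @seealso \code{\link{detectTailBeats}} for whole traces.
#' @export
setMethod("detectTailBeat", signature("BoutDetector", "numeric"),
  function(detector, angle) {
    if (!is.finite(angle)) stop("tail angle must be finite")
    d <- detector
    d@frameIndex <- d@frameIndex + 1L
    d@window <- c(tail(d@window, d@frameWindow - 1L), angle)
    if (!d@inBout) {
      mn <- min(d@window); mx <- max(d@window)
      if (angle - mn > d@boutThreshold) {
        d@inBout <- TRUE; d@searchDir <- 1L
        d@curExtreme <- angle; d@curExtremeFrame <- d@frameIndex
        d@counter <- 0L; d@boutStart <- d@frameIndex
      } else if (mx - angle > d@boutThreshold) {
        d@inBout <- TRUE; d@searchDir <- -1L
        d@curExtreme <- angle; d@curExtremeFrame <- d@frameIndex
        d@counter <- 0L; d@boutStart <- d@frameIndex
      }
    } else {
      d@counter <- d@counter + 1L
      if (d@searchDir > 0L) {
        if (angle > d@curExtreme) {
          d@curExtreme <- angle; d@curExtremeFrame <- d@frameIndex
        }
        if (d@curExtreme - angle > d@peakThreshold) {
          d <- .registerPeak(d, up = TRUE)
          d@searchDir <- -1L
          d@curExtreme <- angle; d@curExtremeFrame <- d@frameIndex
          d@counter <- 0L
        }
      } else {
        if (angle < d@curExtreme) {
          d@curExtreme <- angle; d@curExtremeFrame <- d@frameIndex
        }
        if (angle - d@curExtreme > d@peakThreshold) {
          d <- .registerPeak(d, up = FALSE)
          d@searchDir <- 1L
          d@curExtreme <- angle; d@curExtremeFrame <- d@frameIndex
          d@counter <- 0L
        }
      }
      if (d@counter > d@frameWindow) {
        d@inBout <- FALSE; d@counter <- 0L; d@searchDir <- 0L
        d@frequency <- 0; d@amplitude <- 0
        d@lastPeakUp <- NA_integer_; d@lastPeakDown <- NA_integer_
        d@lastPeakAny <- NA_integer_; d@boutStart <- NA_integer_
      }
    }
    list(detector = d,
         kinematics = list(frequency = if (d@inBout) d@frequency else 0,
                           amplitude = if (d@inBout) d@amplitude else 0,
                           bout = d@inBout))
  })

.registerPeak <- function(d, up) {
  pf <- d@curExtremeFrame
  d@amplitude <- d@curExtreme
  if (d@cycleMode == "full") {
    prev <- if (up) d@lastPeakUp else d@lastPeakDown
    if (!is.na(prev) && pf > prev) d@frequency <- d@frameRate / (pf - prev)
    if (up) d@lastPeakUp <- pf else d@lastPeakDown <- pf
  } else {
    if (!is.na(d@lastPeakAny) && pf > d@lastPeakAny)
      d@frequency <- d@frameRate / (2 * (pf - d@lastPeakAny))
  }
  d@lastPeakAny <- pf
  d
}

#' Run the bout detector over a whole trace
#'
#' @param detector a \code{\linkS4class{BoutDetector}} (fresh state).
#' @param angles per-frame tail angles, rad.
#' @return data.frame: \code{frame} (0-based), \code{angle},
#'   \code{bout}, \code{frequency}, \code{amplitude}.
#' @export
detectTailBeats <- function(detector, angles) {
  n <- length(angles)
  bout <- logical(n); freq <- amp <- numeric(n)
  for (i in seq_len(n)) {
    r <- detectTailBeat(detector, angles[i])
    detector <- r$detector
    bout[i] <- r$kinematics$bout
    freq[i] <- r$kinematics$frequency
    amp[i] <- r$kinematics$amplitude
  }
  data.frame(frame = 0:(n - 1), angle = angles, bout = bout,
             frequency = freq, amplitude = amp)
}

setMethod("show", "BoutDetector", function(object) {
  cat("BoutDetector @", object@frameRate, "Hz: boutThreshold",
      object@boutThreshold, "rad, peakThreshold", object@peakThreshold,
      "rad, window", object@frameWindow, "frames,", object@cycleMode,
      "cycle\n")
  cat(if (object@inBout) "  state: in bout\n" else "  state: quiescent\n")
})
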