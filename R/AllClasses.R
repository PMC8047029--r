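## S4 classes for the stateful objects of the tracking stack.

#' Running-extremum background model
#'
#' Holds the per-pixel darkest or lightest intensity seen so far. Updated
#' frame by frame with \code{\link{updateBackground}}; the modeled scene is
#' recovered wherever the animal has moved away at least once.
#'
#' @slot image numeric matrix of background intensities (0--255); empty until
#'   the first update.
#' @slot pixelSearch \code{"darkest"} or \code{"lightest"}: which extremum is
#'   maintained. Use \code{"lightest"} for a dark animal on a light arena.
#' @slot noiseThreshold non-negative intensity margin a pixel must exceed the
#'   stored extremum by before the background updates.
#' @seealso \code{\link{updateBackground}}, \code{\link{subtractBackground}}
#' @export
setClass("BackgroundModel",
  representation(image = "matrix", pixelSearch = "character",
                 noiseThreshold = "numeric"),
  prototype(image = matrix(numeric(0), 0, 0), pixelSearch = "lightest",
            noiseThreshold = 0),
  validity = function(object) {
    msg <- character(0)
    if (!object@pixelSearch %in% c("darkest", "lightest"))
      msg <- c(msg, "pixelSearch must be 'darkest' or 'lightest'")
    if (length(object@noiseThreshold) != 1 || object@noiseThreshold < 0)
      msg <- c(msg, "noiseThreshold must be a single non-negative number")
    if (length(msg)) msg else TRUE
  })

#' Configuration for iterative tail-point fitting
#'
#' Parameters of the point-to-point contrast search that fits an ordered
#' polyline from the body centroid to the tail tip.
#'
#' @slot distTailBase radius (px) of the circle searched for the first tail
#'   point, seeded at the centroid.
#' @slot distTailPoints radius (px) of the circle searched for every
#'   subsequent point, seeded at the previous point.
#' @slot rangeTailPointAngles angular length (rad) of the search arc for
#'   subsequent points, centered on the continuation of the previous segment.
#' @slot numTailSegments number of tail segments; the fitted polyline has
#'   \code{numTailSegments + 2} points (centroid, tail base, segment ends).
#' @slot method point scoring: \code{"pixel_search"} (extremum pixel),
#'   \code{"weighted_median"} (contrast-weighted median along the arc) or
#'   \code{"center_of_mass"} (arc point nearest the contrast center of mass).
#' @slot pixelPolarity \code{"darkest"} if the fish is dark on a light
#'   background, \code{"lightest"} for the inverse.
#' @slot headingDirection known heading (rad, counterclockwise-positive); any
#'   negative value means "unset" and triggers a full-circle search for the
#'   first tail point.
#' @slot offsetX,offsetY constants added to the fitted x and y coordinates.
#' @seealso \code{\link{calculateTailPoints}}
#' @export
setClass("TailFitConfig",
  representation(distTailBase = "numeric", distTailPoints = "numeric",
                 rangeTailPointAngles = "numeric", numTailSegments = "integer",
                 method = "character", pixelPolarity = "character",
                 headingDirection = "numeric",
                 offsetX = "numeric", offsetY = "numeric"),
  prototype(distTailBase = 12, distTailPoints = 6,
            rangeTailPointAngles = 2 * pi / 3, numTailSegments = 7L,
            method = "pixel_search", pixelPolarity = "darkest",
            headingDirection = -1, offsetX = 0, offsetY = 0),
  validity = function(object) {
    msg <- character(0)
    if (object@distTailBase < 1 || object@distTailPoints < 1)
      msg <- c(msg, "search radii must be >= 1 px")
    if (object@rangeTailPointAngles <= 0 || object@rangeTailPointAngles > 2 * pi)
      msg <- c(msg, "rangeTailPointAngles must lie in (0, 2*pi]")
    if (object@numTailSegments < 1L)
      msg <- c(msg, "numTailSegments must be >= 1")
    if (!object@method %in% c("pixel_search", "weighted_median", "center_of_mass"))
      msg <- c(msg, "unknown tail point method")
    if (!object@pixelPolarity %in% c("darkest", "lightest"))
      msg <- c(msg, "pixelPolarity must be 'darkest' or 'lightest'")
    if (length(msg)) msg else TRUE
  })

#' Online bout and tail-beat detector state
#'
#' Streaming detector that compares each incoming tail angle against the
#' running extrema of a short window, flags bout instances, finds alternating
#' inflection peaks, and converts inter-peak spacing to a tail-beat frequency.
#'
#' @slot boutThreshold excursion (rad) from the running extremum that starts
#'   a bout.
#' @slot peakThreshold reversal (rad) from the running extremum that confirms
#'   an inflection peak.
#' @slot frameWindow frames retained in the running window; also the number of
#'   quiet frames after which a bout expires.
#' @slot frameRate acquisition rate, Hz.
#' @slot cycleMode \code{"full"}: frequency from same-direction peak spacing
#'   (one full oscillation cycle, so a 20 Hz sine reads 20 Hz);
#'   \code{"half"}: from successive alternating peaks, doubled.
#' @slot window,frameIndex,inBout,counter,searchDir,curExtreme,curExtremeFrame,lastPeakUp,lastPeakDown,lastPeakAny,frequency,amplitude,boutStart
#'   internal streaming state; read via \code{\link{detectTailBeat}} outputs.
#' @seealso \code{\link{boutDetector}}, \code{\link{detectTailBeat}}
#' @export
setClass("BoutDetector",
  representation(boutThreshold = "numeric", peakThreshold = "numeric",
                 frameWindow = "integer", frameRate = "numeric",
                 cycleMode = "character",
                 window = "numeric", frameIndex = "integer",
                 inBout = "logical", counter = "integer",
                 searchDir = "integer", curExtreme = "numeric",
                 curExtremeFrame = "integer",
                 lastPeakUp = "integer", lastPeakDown = "integer",
                 lastPeakAny = "integer",
                 frequency = "numeric", amplitude = "numeric",
                 boutStart = "integer"),
  prototype(boutThreshold = 0.1, peakThreshold = 0.05, frameWindow = 50L,
            frameRate = 332, cycleMode = "full",
            window = numeric(0), frameIndex = -1L, inBout = FALSE,
            counter = 0L, searchDir = 0L, curExtreme = 0,
            curExtremeFrame = NA_integer_, lastPeakUp = NA_integer_,
            lastPeakDown = NA_integer_, lastPeakAny = NA_integer_,
            frequency = 0, amplitude = 0, boutStart = NA_integer_),
  validity = function(object) {
    msg <- character(0)
    if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
    if (object@frameWindow < 1L) msg <- c(msg, "frameWindow must be >= 1")
    if (object@boutThreshold <= 0 || object@peakThreshold <= 0)
      msg <- c(msg, "thresholds must be positive")
    if (!object@cycleMode %in% c("full", "half"))
      msg <- c(msg, "cycleMode must be 'full' or 'half'")
    if (length(msg)) msg else TRUE
  })

#' One-dimensional closed-loop feedback configuration
#'
#' Parameters of the head-fixed optomotor feedback law
#' \eqn{V_S = V_B - gain \cdot vigor}, where swim vigor is the
#' exponentially-weighted short-window mean of the tail-angle derivative,
#' gated by bout instance.
#'
#' @slot baselineVelocity grating baseline velocity \eqn{V_B}, mm/s.
#' @slot gain dimensionless reafference gain.
#' @slot windowMs integration window, ms (15 ms default).
#' @slot decayMs exponential decay time constant, ms (9 ms default); sample
#'   \eqn{\Delta t} ms in the past is weighted \eqn{e^{-\Delta t / decayMs}}.
#' @slot frameRate acquisition rate, Hz.
#' @slot vigorScale mm/s per unit of raw vigor; calibrated once per
#'   (frameRate, window, decay) so a sustained 20 Hz unit-amplitude bout maps
#'   to 20 mm/s of forward translation at gain 1
#'   (\code{\link{calibrateVigorScale}}). \code{NA} until calibrated.
#' @slot signedVigor if \code{FALSE} (default) the magnitude of the tail-angle
#'   derivative is integrated, so any beat slows the grating; \code{TRUE}
#'   keeps the sign.
#' @seealso \code{\link{swimVigor}}, \code{\link{stimulusVelocity1D}}
#' @export
setClass("FeedbackConfig1D",
  representation(baselineVelocity = "numeric", gain = "numeric",
                 windowMs = "numeric", decayMs = "numeric",
                 frameRate = "numeric", vigorScale = "numeric",
                 signedVigor = "logical"),
  prototype(baselineVelocity = 10, gain = 1, windowMs = 15, decayMs = 9,
            frameRate = 332, vigorScale = NA_real_, signedVigor = FALSE),
  validity = function(object) {
    msg <- character(0)
    if (!is.finite(object@baselineVelocity))
      msg <- c(msg, "baselineVelocity must be finite")
    if (object@decayMs <= 0) msg <- c(msg, "decayMs must be positive")
    if (object@windowMs <= 0) msg <- c(msg, "windowMs must be positive")
    if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
    if (length(msg)) msg else TRUE
  })

#' Two-dimensional closed-loop feedback configuration
#'
#' Parameters of the multi-animal feedback law
#' \eqn{V_S = V_B - boxcar(F) \cdot gain \cdot (1 - |\theta|/90)} with
#' stimulus orientation \eqn{\theta \in [-180, 180)} degrees relative to the
#' heading, plus the angular-velocity law
#' \eqn{V_\theta = \overline{TC} / (t - t_0)}.
#'
#' @slot baselineVelocity baseline velocity \eqn{V_B}, mm/s.
#' @slot gain dimensionless gain.
#' @slot boxcarMs moving-average window applied to tail-beat frequency, ms
#'   (15 ms default, paralleling the one-dimensional window).
#' @slot frameRate acquisition rate, Hz.
#' @slot segments number of tail segments averaged for the curvature term.
#' @seealso \code{\link{stimulusVelocity2D}},
#'   \code{\link{stimulusAngularVelocity}}
#' @export
setClass("FeedbackConfig2D",
  representation(baselineVelocity = "numeric", gain = "numeric",
                 boxcarMs = "numeric", frameRate = "numeric",
                 segments = "integer"),
  prototype(baselineVelocity = 10, gain = 1, boxcarMs = 15, frameRate = 332,
            segments = 1L),
  validity = function(object) {
    msg <- character(0)
    if (object@boxcarMs <= 0) msg <- c(msg, "boxcarMs must be positive")
    if (object@frameRate <= 0) msg <- c(msg, "frameRate must be positive")
    if (object@segments < 1L) msg <- c(msg, "segments must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' Cumulative heading-angle state
#'
#' Accumulates the instantaneous heading across frames with cross-frame
#' unwrapping, so the reported heading is unbounded (a fish turning 10
#' degrees per frame for 72 frames reads 720 degrees, not 0).
#'
#' @slot cumulative unwrapped cumulative heading, rad; \code{NA} before the
#'   first sample.
#' @slot lastInstantaneous last wrapped instantaneous heading, rad.
#' @slot initializeToZero if \code{TRUE} the first sample reports exactly 0
#'   and later samples are relative to it.
#' @seealso \code{\link{calculateHeading}}
#' @export
setClass("HeadingState",
  representation(cumulative = "numeric", lastInstantaneous = "numeric",
                 initializeToZero = "logical"),
  prototype(cumulative = NA_real_, lastInstantaneous = NA_real_,
            initializeToZero = FALSE))

#' Synthetic fish pose
#'
#' Ground-truth description of a rendered fish: centroid, heading, tail
#' shape as inter-segment angles, two eye ellipses, and the two intensity
#' levels that give the contrast the tracker relies on.
#'
#' @slot centroid length-2 numeric, body-centroid pixel coordinates (0-based).
#' @slot heading heading angle, rad, counterclockwise-positive, 0 = +x.
#' @slot segmentAngles inter-segment angles (rad) of the tail, relative to
#'   the caudal direction (heading + pi); all zeros give a straight tail.
#' @slot distTailBase,distTailPoints spacing (px) of the ground-truth tail
#'   polyline: centroid to tail base, then between successive points.
#' @slot eyeDistance,eyeBearing,eyeAxes placement and semi-axes (px) of the
#'   two eye ellipses, rostral of the centroid at \code{+/- eyeBearing} off
#'   the heading.
#' @slot bodyAxes semi-axes (px) of the body ellipse centered on the centroid.
#' @slot bodyIntensity,backgroundIntensity 8-bit intensity levels; they must
#'   differ by at least 20 so contrast detection is well posed.
#' @slot tailWidth Gaussian stroke sigma is derived from this full width (px).
#' @seealso \code{\link{fishPose}}, \code{\link{renderFishFrame}}
#' @export
setClass("FishPose",
  representation(centroid = "numeric", heading = "numeric",
                 segmentAngles = "numeric",
                 distTailBase = "numeric", distTailPoints = "numeric",
                 eyeDistance = "numeric", eyeBearing = "numeric",
                 eyeAxes = "numeric", bodyAxes = "numeric",
                 bodyIntensity = "numeric", backgroundIntensity = "numeric",
                 tailWidth = "numeric"),
  prototype(centroid = c(80, 80), heading = 0, segmentAngles = numeric(7),
            distTailBase = 12, distTailPoints = 6,
            eyeDistance = 4.5, eyeBearing = pi / 6, eyeAxes = c(2.4, 1.4),
            bodyAxes = c(7.5, 4.5), bodyIntensity = 30,
            backgroundIntensity = 220, tailWidth = 3),
  validity = function(object) {
    msg <- character(0)
    if (length(object@centroid) != 2) msg <- c(msg, "centroid must be length 2")
    if (length(object@segmentAngles) < 1)
      msg <- c(msg, "at least one tail segment is required")
    if (abs(object@bodyIntensity - object@backgroundIntensity) < 20)
      msg <- c(msg, "body and background intensity must differ by >= 20")
    if (any(c(object@bodyIntensity, object@backgroundIntensity) < 0) ||
        any(c(object@bodyIntensity, object@backgroundIntensity) > 255))
      msg <- c(msg, "intensities must lie in [0, 255]")
    if (object@eyeDistance <= 0)
      msg <- c(msg, "eyes must lie rostral to the centroid (eyeDistance > 0)")
    if (length(msg)) msg else TRUE
  })
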