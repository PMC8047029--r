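#' Create a running-extremum background model
#'
#' @param pixelSearch \code{"lightest"} (keep the brightest value ever seen at
#'   each pixel; appropriate for a dark animal on a light arena) or
#'   \code{"darkest"} (the mirror case).
#' @param noiseThreshold intensity margin: a pixel must beat the stored value
#'   by strictly more than this amount before the background updates. Ties and
#'   sub-threshold excursions leave the background unchanged.
#' @return a \code{\linkS4class{BackgroundModel}}; its image is empty until
#'   the first \code{\link{updateBackground}} call, which adopts that frame
#'   wholesale.
#' @examples
#' bg <- backgroundModel("lightest", noiseThreshold = 0)
#' f1 <- matrix(100, 4, 4); f2 <- matrix(120, 4, 4)
#' bg <- updateBackground(bg, f1)
#' bg <- updateBackground(bg, f2)
#' backgroundImage(bg)[1, 1]  # 120
#' @export
backgroundModel <- function(pixelSearch = c("lightest", "darkest"),
                            noiseThreshold = 0) {
  pixelSearch <- match.arg(pixelSearch)
  new("BackgroundModel", pixelSearch = pixelSearch,
      noiseThreshold = noiseThreshold)
}

#' Background image accessor
#'
#' @param model a \code{\linkS4class{BackgroundModel}}.
#' @return the current background as a numeric matrix (empty before the first
#'   update).
#' @export
setMethod("backgroundImage", "BackgroundModel", function(model) model@image)

#' Update the running-extremum background with one frame
#'
#' Pixel-wise, in \code{"lightest"} mode the stored value b becomes f when
#' \code{f > b + noiseThreshold}, otherwise it is kept; \code{"darkest"} mode
#' mirrors the rule with \code{f < b - noiseThreshold}. The first frame
#' initializes the background.
#'
#' @param model a \code{\linkS4class{BackgroundModel}}.
#' @param frame numeric matrix with the same dimensions as the model image.
#' @return the updated model.
#' @export
setMethod("updateBackground", signature("BackgroundModel", "matrix"),
  function(model, frame) {
    stopifnotFrame(frame)
    if (length(model@image) == 0) {
      model@image <- frame
      return(model)
    }
    if (!sameDims(model@image, frame))
      stop("frame dimensions do not match the background model")
    b <- model@image
    if (model@pixelSearch == "lightest") {
      upd <- frame > b + model@noiseThreshold
    } else {
      upd <- frame < b - model@noiseThreshold
    }
    b[upd] <- frame[upd]
    model@image <- b
    model
  })

#' Background subtraction
#'
#' Returns the foreground under the stored polarity: with a
#' \code{"lightest"} background (dark subject) the result is
#' \code{clamp(background - frame, 0, 255)}, so subject pixels come out
#' bright and the static scene maps to ~0; \code{"darkest"} mode mirrors.
#'
#' @param frame numeric matrix, same dimensions as the background.
#' @param model a \code{\linkS4class{BackgroundModel}} with an initialized
#'   image.
#' @return foreground frame, never negative.
#' @export
setMethod("subtractBackground", signature("matrix", "BackgroundModel"),
  function(frame, model) {
    if (length(model@image) == 0) stop("background model is uninitialized")
    if (!sameDims(model@image, frame))
      stop("frame dimensions do not match the background model")
    if (model@pixelSearch == "lightest") {
      clamp(model@image - frame, 0, 255)
    } else {
      clamp(frame - model@image, 0, 255)
    }
  })

setMethod("show", "BackgroundModel", function(object) {
  d <- dim(object@image)
  cat("BackgroundModel (", object@pixelSearch, ", noiseThreshold=",
      object@noiseThreshold, ")\n", sep = "")
  if (length(object@image)) {
    cat("  image:", d[2], "x", d[1], "px, range [",
        round(min(object@image), 1), ",", round(max(object@image), 1), "]\n")
  } else cat("  image: <uninitialized>\n")
})
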