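## Generics for the S4 surface.

#' @rdname updateBackground
#' @export
setGeneric("updateBackground", function(model, frame)
  standardGeneric("updateBackground"))

#' @rdname subtractBackground
#' @export
setGeneric("subtractBackground", function(frame, model)
  standardGeneric("subtractBackground"))

#' @rdname detectTailBeat
#' @export
setGeneric("detectTailBeat", function(detector, angle)
  standardGeneric("detectTailBeat"))

#' @rdname renderFishFrame
#' @export
setGeneric("renderFishFrame", function(pose, size)
  standardGeneric("renderFishFrame"))

#' @rdname backgroundImage
#' @export
setGeneric("backgroundImage", function(model) standardGeneric("backgroundImage"))
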