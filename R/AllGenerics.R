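#' @rdname SliceRecord-accessors
#' @export
setGeneric("sliceId", function(x) standardGeneric("sliceId"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("sliceImage", function(x) standardGeneric("sliceImage"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("spacingMm", function(x) standardGeneric("spacingMm"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("nodules", function(x) standardGeneric("nodules"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("noduleMask", function(x) standardGeneric("noduleMask"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("lungMask", function(x) standardGeneric("lungMask"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("qualityMetrics", function(x) standardGeneric("qualityMetrics"))
#' @rdname SliceRecord-accessors
#' @export
setGeneric("qualityTier", function(x) standardGeneric("qualityTier"))

#' @rdname scoreManual
#' @export
setGeneric("scoreManual", function(x, ...) standardGeneric("scoreManual"))

#' @rdname scoreModel
#' @export
setGeneric("scoreModel", function(x, params = modelDifficultyParams(), ...)
    standardGeneric("scoreModel"))

#' @rdname meanConfidence
#' @export
setGeneric("meanConfidence", function(x, ...) standardGeneric("meanConfidence"))
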