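#' Accessors for slice records and slice sets
#'
#' Read access to the slots of \linkS4class{SliceRecord},
#' \linkS4class{QualityMetrics} and per-slice summaries of
#' \linkS4class{SliceSet}.
#'
#' @param x a \code{SliceRecord}, \code{SliceSet} or \code{QualityMetrics}.
#' @return The slot value; for a \code{SliceSet}, a vector with one entry
#'   per slice.
#' @name SliceRecord-accessors
#' @aliases sliceId patientId sliceImage spacingMm nodules noduleMask
#'   lungMask qualityMetrics qualityTier
NULL

#' @rdname SliceRecord-accessors
setMethod("sliceId", "SliceRecord", function(x) x@sliceId)
#' @rdname SliceRecord-accessors
setMethod("patientId", "SliceRecord", function(x) x@patientId)
#' @rdname SliceRecord-accessors
setMethod("sliceImage", "SliceRecord", function(x) x@image)
#' @rdname SliceRecord-accessors
setMethod("spacingMm", "SliceRecord", function(x) x@spacingMm)
#' @rdname SliceRecord-accessors
setMethod("nodules", "SliceRecord", function(x) x@nodules)
#' @rdname SliceRecord-accessors
setMethod("noduleMask", "SliceRecord", function(x) x@mask)
#' @rdname SliceRecord-accessors
setMethod("lungMask", "SliceRecord", function(x) x@lungMask)
#' @rdname SliceRecord-accessors
setMethod("qualityMetrics", "SliceRecord", function(x) x@quality)
#' @rdname SliceRecord-accessors
setMethod("qualityTier", "QualityMetrics", function(x) x@qualityTier)
#' @rdname SliceRecord-accessors
setMethod("qualityTier", "SliceRecord", function(x) {
    if (is.null(x@quality)) NA_character_ else x@quality@qualityTier
})

#' @rdname SliceRecord-accessors
setMethod("sliceId", "SliceSet", function(x)
    vapply(x@slices, function(s) s@sliceId, character(1)))
#' @rdname SliceRecord-accessors
setMethod("patientId", "SliceSet", function(x)
    vapply(x@slices, function(s) s@patientId, character(1)))
#' @rdname SliceRecord-accessors
setMethod("qualityTier", "SliceSet", function(x)
    vapply(x@slices, function(s)
        if (is.null(s@quality)) NA_character_ else s@quality@qualityTier,
        character(1)))

#' @export
setMethod("length", "SliceSet", function(x) length(x@slices))

#' @export
setMethod("[", "SliceSet", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, sliceId(x))
    new("SliceSet", slices = x@slices[i])
})

#' @export
setMethod("[[", "SliceSet", function(x, i, j, ...) {
    if (is.character(i)) i <- match(i, sliceId(x))
    x@slices[[i]]
})

#' Combine slice sets
#'
#' Concatenates several \linkS4class{SliceSet} objects; slice ids must stay
#' unique across the result.
#'
#' @param ... \code{SliceSet} objects.
#' @return A single \code{SliceSet}.
#' @export
combineSliceSets <- function(...) {
    sets <- list(...)
    stopifnot(all(vapply(sets, is, logical(1), "SliceSet")))
    new("SliceSet", slices = do.call(c, lapply(sets, function(s) s@slices)))
}

#' Number of nodules per slice
#'
#' @param x a \code{SliceSet}.
#' @return Integer vector, one count per slice.
#' @export
noduleCounts <- function(x) {
    stopifnot(is(x, "SliceSet"))
    vapply(x@slices, function(s) nrow(s@nodules), integer(1))
}

setMethod("show", "SliceRecord", function(object) {
    cat(sprintf("SliceRecord %s (patient %s): %dx%d px, %.2f mm/px, %d nodule(s)%s\n",
        object@sliceId, object@patientId,
        nrow(object@image), ncol(object@image), object@spacingMm,
        nrow(object@nodules),
        if (is.null(object@quality)) ""
        else sprintf(", quality %s", object@quality@qualityTier)))
})

setMethod("show", "SliceSet", function(object) {
    n <- length(object@slices)
    np <- length(unique(patientId(object)))
    pos <- sum(noduleCounts(object) > 0L)
    cat(sprintf("SliceSet: %d slice(s) from %d patient(s); %d nodule-bearing, %d negative\n",
        n, np, pos, n - pos))
})

setMethod("show", "QualityMetrics", function(object) {
    cat(sprintf(paste0("QualityMetrics: tier %s (lungCoverage %.3f, ",
                       "laplacianVariance %.1f, contrast %.1f)\n"),
        object@qualityTier, object@lungCoverage,
        object@laplacianVariance, object@contrast))
})

setMethod("show", "DetectionSummary", function(object) {
    cat(sprintf("DetectionSummary %s: %d post-NMS box(es), nGt = %d, %d pre-NMS score(s)\n",
        object@sliceId, nrow(object@boxes), object@nGt,
        length(object@preNmsScores)))
})

setMethod("show", "StageConfig", function(object) {
    cat(sprintf("StageConfig %d: %d px, %d epochs, lr %.4g; tiers {%s}; negatives {%s}\n",
        object@stageIndex, object@inputResolution, object@epochs,
        object@learningRate,
        paste(object@includedTiers, collapse = ","),
        paste(object@includedNegativeQuality, collapse = ",")))
})

setMethod("show", "CurriculumManifest", function(object) {
    ns <- vapply(object@stages, length, integer(1))
    cat(sprintf("CurriculumManifest: stage sizes %s (a = %s)\n",
        paste(ns, collapse = " / "),
        format(object@provenance$a %||% NA)))
})

setMethod("show", "EvalResult", function(object) {
    cat(sprintf(paste0("EvalResult: mAP50 %.4f, mAP50-95 %.4f, ",
                       "precision %.4f, recall %.4f (TP %d, FP %d, FN %d)\n"),
        object@map50, object@map50_95, object@precision, object@recall,
        object@counts[["tp"]], object@counts[["fp"]], object@counts[["fn"]]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
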