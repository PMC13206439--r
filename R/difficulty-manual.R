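# Handcrafted per-slice difficulty: the sum of four clinically
# interpretable factors (nodule count, size, shape irregularity, image
# quality). Factor values are fixed design rules; the sum always lies in
# [2.0, 11.0].

#' Nodule-count difficulty factor
#'
#' 0.5 for nodule-free slices, 1.0 for a single nodule, 2.5 for 2-3
#' nodules, 4.0 for 4 or more.
#'
#' @param nNodules integer vector of per-slice nodule counts.
#' @return Numeric factor values in \{0.5, 1.0, 2.5, 4.0\}.
#' @export
countFactor <- function(nNodules) {
    stopifnot(all(nNodules >= 0))
    ifelse(nNodules == 0L, 0.5,
    ifelse(nNodules == 1L, 1.0,
    ifelse(nNodules <= 3L, 2.5, 4.0)))
}

#' Nodule-size difficulty factor
#'
#' Governed by the smallest nodule on the slice: 0.5 when no nodule is
#' present, 1.0 when the minimum nodule area exceeds 1000 px, 2.0 for
#' minimum areas in the 400-1000 px band (both bounds included), 3.0 for
#' smaller nodules. Areas are mask foreground counts when a mask exists,
#' else box areas, measured at the stored 512x512-scale resolution.
#'
#' @param areasPx numeric vector of per-nodule areas (pixels squared) of
#'   one slice; may be empty.
#' @return Scalar factor value in \{0.5, 1.0, 2.0, 3.0\}.
#' @export
sizeFactor <- function(areasPx) {
    if (!length(areasPx)) return(0.5)
    a <- min(areasPx)
    if (a > 1000) 1.0 else if (a >= 400) 2.0 else 3.0
}

#' Shape-irregularity difficulty factor
#'
#' A nodule is irregular when its box aspect ratio exceeds the threshold
#' (default 2.0, a conventional elongation cutoff). The factor is 0.5 with
#' no irregular nodule, 1.0 with exactly one, 2.0 with several.
#'
#' @param aspectRatios numeric vector of per-nodule aspect ratios
#'   (>= 1) of one slice; may be empty.
#' @param threshold irregularity cutoff on the aspect ratio.
#' @return Scalar factor value in \{0.5, 1.0, 2.0\}.
#' @export
shapeFactor <- function(aspectRatios, threshold = 2.0) {
    nIrr <- sum(aspectRatios > threshold)
    if (nIrr == 0L) 0.5 else if (nIrr == 1L) 1.0 else 2.0
}

#' Image-quality difficulty factor
#'
#' 0.5 for sharp, high-contrast slices (quality tier high: Laplacian
#' variance > 500 and contrast > 30), 1.0 for medium quality, 2.0 for
#' blurry or low-contrast slices.
#'
#' @param tier quality tier string(s): "high", "medium" or "low"; a
#'   \linkS4class{QualityMetrics} or quality-carrying
#'   \linkS4class{SliceRecord} is also accepted.
#' @return Numeric factor values in \{0.5, 1.0, 2.0\}.
#' @export
qualityFactor <- function(tier) {
    if (is(tier, "QualityMetrics")) tier <- tier@qualityTier
    if (is(tier, "SliceRecord")) tier <- qualityTier(tier)
    stopifnot(all(tier %in% c("high", "medium", "low")))
    c(high = 0.5, medium = 1.0, low = 2.0)[tier]
}

#' Handcrafted difficulty score
#'
#' Sums the four handcrafted factors
#' \deqn{c_{manual} = f_{cnt} + f_{size} + f_{shape} + f_{qual}}
#' for one slice or for every slice of a set. Components are returned
#' alongside the sum for audit. The sum always lies in [2.0, 11.0].
#'
#' @param x a \linkS4class{SliceRecord} or \linkS4class{SliceSet} with
#'   quality computed.
#' @param shapeThreshold aspect-ratio irregularity cutoff passed to
#'   \code{\link{shapeFactor}}.
#' @param ... unused.
#' @return data.frame with columns \code{sliceId, fCnt, fSize, fShape,
#'   fQual, cManual} (one row for a record).
#' @examples
#' ss <- computeQualitySet(generateDataset(
#'     fixtureSpec(nPatients = 2L, slicesPerPatient = 2L, imageSize = 96L)))
#' scoreManual(ss)
#' @rdname scoreManual
#' @export
setMethod("scoreManual", "SliceRecord", function(x, shapeThreshold = 2.0, ...) {
    if (is.null(x@quality))
        stop(sprintf("quality not computed for slice %s", x@sliceId))
    nd <- x@nodules
    fc <- countFactor(nrow(nd))
    fs <- sizeFactor(nd$areaPx)
    fh <- shapeFactor(nd$aspectRatio, shapeThreshold)
    fq <- unname(qualityFactor(x@quality@qualityTier))
    data.frame(sliceId = x@sliceId, fCnt = fc, fSize = fs, fShape = fh,
               fQual = fq, cManual = fc + fs + fh + fq)
})

#' @rdname scoreManual
#' @export
setMethod("scoreManual", "SliceSet", function(x, shapeThreshold = 2.0, ...) {
    out <- do.call(rbind, lapply(x@slices, scoreManual,
                                 shapeThreshold = shapeThreshold))
    rownames(out) <- NULL
    out
})
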