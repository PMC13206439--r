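#' @import methods
#' @importFrom stats rnorm runif rbeta rpois sd var setNames
#' @importFrom utils head
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Per-slice image quality metrics
#'
#' Holds the scalar quality metrics computed over the lung region of one CT
#' slice and the quality tier they imply. The tier is \code{"high"} iff
#' Laplacian variance exceeds 500 and contrast exceeds 30 (8-bit intensity
#' units), \code{"low"} iff either metric falls at or below the configured
#' low boundary, and \code{"medium"} otherwise.
#'
#' @slot lungCoverage fraction of image pixels inside the lung region, in [0, 1].
#' @slot intensityHeterogeneity standard deviation of 8-bit intensities
#'   within the lung region.
#' @slot laplacianVariance variance of the 3x3 discrete Laplacian response
#'   within the lung region (intensity squared); the standard sharpness measure.
#' @slot contrast intensity standard deviation within the lung region
#'   (8-bit units), the scalar compared against the 30 / 15 thresholds.
#' @slot qualityTier one of \code{"high"}, \code{"medium"}, \code{"low"}.
#' @export
setClass("QualityMetrics",
    representation(
        lungCoverage = "numeric",
        intensityHeterogeneity = "numeric",
        laplacianVariance = "numeric",
        contrast = "numeric",
        qualityTier = "character"
    ),
    validity = function(object) {
        msg <- character()
        if (object@lungCoverage < 0 || object@lungCoverage > 1)
            msg <- c(msg, "lungCoverage must lie in [0, 1]")
        if (object@laplacianVariance < 0)
            msg <- c(msg, "laplacianVariance must be non-negative")
        if (!object@qualityTier %in% c("high", "medium", "low"))
            msg <- c(msg, "qualityTier must be 'high', 'medium' or 'low'")
        if (length(msg)) msg else TRUE
    }
)

setClassUnion("QualityMetricsOrNULL", c("QualityMetrics", "NULL"))

#' One annotated CT slice
#'
#' The unit record of the toolkit: a single 2D grayscale slice with its
#' patient provenance, in-plane pixel spacing, nodule annotations and
#' (optionally) segmentation/lung masks and quality metrics.
#'
#' Boxes use a 0-based, half-open pixel convention: a box
#' \code{[xmin, xmax) x [ymin, ymax)} with x = column and y = row, so its
#' area is \code{(xmax - xmin) * (ymax - ymin)} exactly.
#'
#' @slot sliceId character scalar, unique within a dataset.
#' @slot patientId character scalar.
#' @slot image numeric matrix of 8-bit intensities (0-255), rows = y,
#'   columns = x.
#' @slot spacingMm isotropic in-plane pixel spacing in mm/pixel.
#' @slot nodules data.frame with one row per nodule: \code{xmin, ymin, xmax,
#'   ymax} (pixels, half-open), \code{areaPx} (mask foreground count if a
#'   mask exists, else box area) and \code{aspectRatio}
#'   (\code{max(w/h, h/w)}, always >= 1).
#' @slot mask optional binary nodule segmentation mask (same shape as image).
#' @slot lungMask optional binary lung-region mask; when absent the whole
#'   image is treated as lung for quality metrics.
#' @slot quality optional \linkS4class{QualityMetrics}.
#' @export
setClass("SliceRecord",
    representation(
        sliceId = "character",
        patientId = "character",
        image = "matrix",
        spacingMm = "numeric",
        nodules = "data.frame",
        mask = "matrixOrNULL",
        lungMask = "matrixOrNULL",
        quality = "QualityMetricsOrNULL"
    ),
    prototype(mask = NULL, lungMask = NULL, quality = NULL),
    validity = function(object) {
        msg <- character()
        if (length(object@sliceId) != 1L || !nzchar(object@sliceId))
            msg <- c(msg, "sliceId must be a non-empty character scalar")
        if (length(object@patientId) != 1L || !nzchar(object@patientId))
            msg <- c(msg, "patientId must be a non-empty character scalar")
        if (length(object@spacingMm) != 1L || is.na(object@spacingMm) ||
            object@spacingMm <= 0)
            msg <- c(msg, "spacingMm must be a positive scalar")
        nd <- object@nodules
        need <- c("xmin", "ymin", "xmax", "ymax", "areaPx", "aspectRatio")
        if (!all(need %in% names(nd)))
            msg <- c(msg, sprintf("nodules must have columns %s",
                                  paste(need, collapse = ", ")))
        else if (nrow(nd)) {
            if (any(nd$xmin >= nd$xmax) || any(nd$ymin >= nd$ymax))
                msg <- c(msg, "nodule boxes must satisfy xmin < xmax, ymin < ymax")
            if (any(nd$aspectRatio < 1))
                msg <- c(msg, "aspectRatio must be >= 1")
            if (any(nd$areaPx <= 0))
                msg <- c(msg, "areaPx must be positive")
        }
        if (!is.null(object@mask) &&
            !identical(dim(object@mask), dim(object@image)))
            msg <- c(msg, "mask must match image dimensions")
        if (!is.null(object@lungMask) &&
            !identical(dim(object@lungMask), dim(object@image)))
            msg <- c(msg, "lungMask must match image dimensions")
        if (length(msg)) msg else TRUE
    }
)

#' A collection of CT slices
#'
#' Ordered container of \linkS4class{SliceRecord} objects with unique slice
#' identifiers. Supports \code{length}, \code{[}, \code{[[} and combination
#' via \code{\link{combineSliceSets}}.
#'
#' @slot slices list of \linkS4class{SliceRecord}.
#' @export
setClass("SliceSet",
    representation(slices = "list"),
    validity = function(object) {
        if (!all(vapply(object@slices, is, logical(1), "SliceRecord")))
            return("all elements must be SliceRecord objects")
        ids <- vapply(object@slices, function(s) s@sliceId, character(1))
        if (anyDuplicated(ids))
            return("slice ids must be unique within a SliceSet")
        TRUE
    }
)

#' Teacher-detector prediction summary for one slice
#'
#' Post-NMS boxes with confidences plus the top pre-NMS candidate scores, as
#' produced by an external (teacher) detector, together with the
#' ground-truth nodule count taken from the annotations. This is the input
#' of the model-driven difficulty score.
#'
#' @slot sliceId character scalar.
#' @slot boxes data.frame of post-NMS boxes (\code{xmin, ymin, xmax, ymax});
#'   may have zero rows.
#' @slot confidences numeric vector in [0, 1], one per box.
#' @slot preNmsScores numeric vector of candidate scores in [0, 1], sorted
#'   in decreasing order; used only when no box survives NMS.
#' @slot nGt integer ground-truth nodule count for the slice.
#' @export
setClass("DetectionSummary",
    representation(
        sliceId = "character",
        boxes = "data.frame",
        confidences = "numeric",
        preNmsScores = "numeric",
        nGt = "integer"
    ),
    validity = function(object) {
        msg <- character()
        if (nrow(object@boxes) != length(object@confidences))
            msg <- c(msg, "one confidence per box is required")
        if (length(object@confidences) &&
            (any(object@confidences < 0) || any(object@confidences > 1)))
            msg <- c(msg, "confidences must lie in [0, 1]")
        if (length(object@preNmsScores)) {
            if (any(object@preNmsScores < 0) || any(object@preNmsScores > 1))
                msg <- c(msg, "preNmsScores must lie in [0, 1]")
            if (is.unsorted(rev(object@preNmsScores)))
                msg <- c(msg, "preNmsScores must be sorted in decreasing order")
        }
        if (object@nGt < 0L)
            msg <- c(msg, "nGt must be non-negative")
        if (length(msg)) msg else TRUE
    }
)

#' Parameters of the model-driven difficulty score
#'
#' Weights and clipping bounds of the model-driven difficulty
#' \deqn{c_{det} = clip(\lambda_1 (1 - \bar p)
#'   + \lambda_2 |N_{pred} - N_{gt}| / \max(N_{gt}, 1)
#'   + \lambda_3 \min(0.5 N_{pred}, 2), c_{low}, c_{high}).}
#' Defaults are \eqn{\lambda_1 = \lambda_2 = 3.0}, \eqn{\lambda_3 = 1.0}
#' and clipping to [0.5, 8.0].
#'
#' @slot lambda1,lambda2,lambda3 non-negative term weights
#'   (confidence, count discrepancy, prediction density).
#' @slot clipLow,clipHigh output clipping bounds, \code{clipLow < clipHigh}.
#' @export
setClass("ModelDifficultyParams",
    representation(
        lambda1 = "numeric", lambda2 = "numeric", lambda3 = "numeric",
        clipLow = "numeric", clipHigh = "numeric"
    ),
    prototype(lambda1 = 3.0, lambda2 = 3.0, lambda3 = 1.0,
              clipLow = 0.5, clipHigh = 8.0),
    validity = function(object) {
        msg <- character()
        if (any(c(object@lambda1, object@lambda2, object@lambda3) < 0))
            msg <- c(msg, "weights must be non-negative")
        if (object@clipLow >= object@clipHigh)
            msg <- c(msg, "clipLow must be smaller than clipHigh")
        if (length(msg)) msg else TRUE
    }
)

#' Training configuration for one curriculum stage
#'
#' Data-inclusion rule plus the training hyperparameters of one progressive
#' stage. The three default stages use input resolutions 512/640/768 px,
#' 50/100/100 epochs and learning rates 0.003/0.002/0.001, with loss-weight
#' and augmentation triples growing in strength; see
#' \code{\link{defaultStageConfigs}}.
#'
#' @slot stageIndex integer in 1..3.
#' @slot inputResolution detector input resolution in pixels.
#' @slot epochs number of training epochs.
#' @slot learningRate initial learning rate.
#' @slot lossWeights named numeric: \code{box}, \code{cls}, \code{dfl}.
#' @slot augmentation named numeric: \code{rotationDeg},
#'   \code{translationFrac}, \code{scaleFrac}.
#' @slot includedTiers character subset of
#'   \code{c("simple", "medium", "complex")} (positives included).
#' @slot includedNegativeQuality character subset of
#'   \code{c("high", "medium", "low")} (negatives included).
#' @export
setClass("StageConfig",
    representation(
        stageIndex = "integer",
        inputResolution = "integer",
        epochs = "integer",
        learningRate = "numeric",
        lossWeights = "numeric",
        augmentation = "numeric",
        includedTiers = "character",
        includedNegativeQuality = "character"
    ),
    validity = function(object) {
        msg <- character()
        if (!object@stageIndex %in% 1:3)
            msg <- c(msg, "stageIndex must be 1, 2 or 3")
        if (!identical(sort(names(object@lossWeights)),
                       sort(c("box", "cls", "dfl"))))
            msg <- c(msg, "lossWeights must be named box, cls, dfl")
        if (!identical(sort(names(object@augmentation)),
                       sort(c("rotationDeg", "translationFrac", "scaleFrac"))))
            msg <- c(msg, paste("augmentation must be named rotationDeg,",
                                "translationFrac, scaleFrac"))
        if (!all(object@includedTiers %in% c("simple", "medium", "complex")))
            msg <- c(msg, "invalid tier in includedTiers")
        if (!all(object@includedNegativeQuality %in% c("high", "medium", "low")))
            msg <- c(msg, "invalid quality tier in includedNegativeQuality")
        if (length(msg)) msg else TRUE
    }
)

#' A three-stage curriculum manifest
#'
#' Per-stage slice-id lists plus the stage configurations and full
#' provenance (mixing coefficient, difficulty weights, tier thresholds,
#' seeds). Stage sample sets are nested
#' (stage 1 \eqn{\subseteq} stage 2 \eqn{\subseteq} stage 3) and stage 3
#' covers the full training set.
#'
#' @slot stages list of three character vectors of slice ids.
#' @slot configs list of three \linkS4class{StageConfig}.
#' @slot provenance named list recording the parameters that produced the
#'   manifest.
#' @export
setClass("CurriculumManifest",
    representation(
        stages = "list",
        configs = "list",
        provenance = "list"
    ),
    validity = function(object) {
        msg <- character()
        if (length(object@stages) != 3L)
            msg <- c(msg, "exactly three stages are required")
        else {
            s <- lapply(object@stages, as.character)
            if (!all(s[[1L]] %in% s[[2L]]) || !all(s[[2L]] %in% s[[3L]]))
                msg <- c(msg, "stage sample sets must be nested")
        }
        if (length(object@configs) &&
            !all(vapply(object@configs, is, logical(1), "StageConfig")))
            msg <- c(msg, "configs must be StageConfig objects")
        if (length(msg)) msg else TRUE
    }
)

#' Detection evaluation result
#'
#' Output of \code{\link{evaluateDetections}}: the precision/recall
#' operating point (confidence >= threshold, IoU 0.5), average precision per
#' IoU threshold, mAP50 and mAP50-95, and the swept precision-recall curves.
#'
#' @slot precision,recall operating-point values in [0, 1].
#' @slot apPerTau named numeric vector, AP at each IoU threshold
#'   0.50, 0.55, ..., 0.95.
#' @slot map50 AP at IoU 0.50.
#' @slot map50_95 mean of the ten AP values.
#' @slot counts named integer vector (\code{tp}, \code{fp}, \code{fn}) at
#'   the operating point.
#' @slot prCurves list of data.frames (recall, precision) per IoU threshold.
#' @slot metadata list recording evaluation conventions (matcher,
#'   integration rule, operating point).
#' @export
setClass("EvalResult",
    representation(
        precision = "numeric",
        recall = "numeric",
        apPerTau = "numeric",
        map50 = "numeric",
        map50_95 = "numeric",
        counts = "integer",
        prCurves = "list",
        metadata = "list"
    ),
    validity = function(object) {
        vals <- c(object@precision, object@recall, object@apPerTau,
                  object@map50, object@map50_95)
        if (any(vals < -1e-12) || any(vals > 1 + 1e-12))
            return("all metric values must lie in [0, 1]")
        TRUE
    }
)

#' Synthetic dataset specification
#'
#' Parameters of the CT-like fixture generator; see
#' \code{\link{fixtureSpec}} for defaults and
#' \code{\link{generateDataset}} for the generator.
#'
#' @slot nPatients,slicesPerPatient counts.
#' @slot noduleCountDist named probability vector over counts 0..5.
#' @slot areaRangePx nodule area interval in pixels squared.
#' @slot aspectRatioRange nodule ellipse aspect-ratio interval (>= 1).
#' @slot blurSigmaRange Gaussian blur sigma interval in pixels.
#' @slot contrastRange lung-region noise amplitude interval (8-bit units).
#' @slot imageSize square image side in pixels.
#' @slot spacingMm in-plane pixel spacing in mm/pixel.
#' @slot seed integer random seed.
#' @export
setClass("FixtureSpec",
    representation(
        nPatients = "integer",
        slicesPerPatient = "integer",
        noduleCountDist = "numeric",
        areaRangePx = "numeric",
        aspectRatioRange = "numeric",
        blurSigmaRange = "numeric",
        contrastRange = "numeric",
        imageSize = "integer",
        spacingMm = "numeric",
        seed = "integer"
    ),
    validity = function(object) {
        msg <- character()
        if (object@nPatients < 1L || object@slicesPerPatient < 1L)
            msg <- c(msg, "nPatients and slicesPerPatient must be positive")
        p <- object@noduleCountDist
        if (!identical(names(p), as.character(0:5)))
            msg <- c(msg, "noduleCountDist must be named '0'..'5'")
        if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
            msg <- c(msg, "noduleCountDist must be a probability vector summing to 1")
        rngs <- list(areaRangePx = object@areaRangePx,
                     aspectRatioRange = object@aspectRatioRange,
                     blurSigmaRange = object@blurSigmaRange,
                     contrastRange = object@contrastRange)
        for (nm in names(rngs)) {
            r <- rngs[[nm]]
            if (length(r) != 2L || r[1L] > r[2L])
                msg <- c(msg, sprintf("%s must be an interval with low <= high", nm))
        }
        if (object@aspectRatioRange[1L] < 1)
            msg <- c(msg, "aspect ratios must be >= 1")
        if (object@imageSize <= 0L)
            msg <- c(msg, "imageSize must be positive")
        if (object@spacingMm <= 0)
            msg <- c(msg, "spacingMm must be positive")
        if (length(msg)) msg else TRUE
    }
)
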