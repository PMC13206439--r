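#' Compute per-slice image quality metrics
#'
#' Evaluates the quality metrics used both for slice triage and for the
#' image-quality difficulty factor: lung coverage (fraction of pixels in
#' the lung region), intensity heterogeneity and contrast (both the
#' standard deviation of 8-bit intensities within the lung region), and the
#' variance of the 3x3 discrete Laplacian response within the lung region
#' (the standard sharpness measure). The quality tier is \code{"high"} iff
#' Laplacian variance > \code{highLap} and contrast > \code{highContrast}
#' (defaults 500 and 30), \code{"low"} iff Laplacian variance <=
#' \code{lowLap} or contrast <= \code{lowContrast} (defaults 150 and 15,
#' the high thresholds scaled down about 3x), and \code{"medium"}
#' otherwise. A constant image scores 0 on both metrics and is tier low.
#'
#' @param record a \linkS4class{SliceRecord}; its \code{lungMask} slot is
#'   used when present.
#' @param lungMask optional binary matrix overriding the record's lung
#'   mask; when neither exists the whole image is treated as lung.
#' @param highLap,highContrast thresholds of the high tier.
#' @param lowLap,lowContrast boundaries of the low tier.
#' @return The record with its \code{quality} slot filled.
#' @export
computeQuality <- function(record, lungMask = NULL,
                           highLap = 500, highContrast = 30,
                           lowLap = 150, lowContrast = 15) {
    stopifnot(is(record, "SliceRecord"))
    img <- record@image
    m <- lungMask %||% record@lungMask
    if (is.null(m)) m <- matrix(1L, nrow(img), ncol(img))
    inside <- m > 0
    cov <- mean(inside)
    vals <- img[inside]
    contrast <- if (length(vals) > 1L) sd(vals) else 0
    if (!is.finite(contrast)) contrast <- 0
    lap <- laplacianResponse(img)[inside]
    lapVar <- if (length(lap) > 1L) var(lap) else 0
    tier <- if (lapVar > highLap && contrast > highContrast) "high"
            else if (lapVar <= lowLap || contrast <= lowContrast) "low"
            else "medium"
    record@quality <- new("QualityMetrics",
        lungCoverage = cov,
        intensityHeterogeneity = contrast,
        laplacianVariance = lapVar,
        contrast = contrast,
        qualityTier = tier)
    record
}

laplacianResponse <- function(img) {
    kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
    as.matrix(EBImage::filter2(img, kern, boundary = "replicate"))
}

#' Compute quality metrics for every slice of a set
#'
#' @param records a \linkS4class{SliceSet}.
#' @param ... passed on to \code{\link{computeQuality}}.
#' @return The \code{SliceSet} with quality filled on every slice.
#' @export
computeQualitySet <- function(records, ...) {
    stopifnot(is(records, "SliceSet"))
    records@slices <- lapply(records@slices, computeQuality, ...)
    records
}

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE to an 8-bit single-channel image (clip limit 2.0 on an
#' 8x8 tile grid by default, the conventional settings) through
#' \code{EBImage::clahe}. HU-valued images must be windowed to 8-bit first
#' (see \code{\link{windowToByte}}). Shape and 8-bit range are preserved; a
#' constant image is returned unchanged (there is no gradient to equalize).
#'
#' @param image numeric matrix with values in 0-255, or a
#'   \linkS4class{SliceRecord} (equalized in place).
#' @param clipLimit CLAHE clip limit.
#' @param tiles number of tiles per side.
#' @return Equalized image of the same shape and type, or the record with
#'   its image equalized.
#' @export
applyClahe <- function(image, clipLimit = 2.0, tiles = 8L) {
    if (is(image, "SliceRecord")) {
        image@image <- applyClahe(image@image, clipLimit, tiles)
        return(image)
    }
    stopifnot(is.matrix(image))
    if (diff(range(image)) == 0) return(image)
    eq <- EBImage::clahe(image / 255, nx = tiles, ny = tiles,
                         limit = clipLimit)
    out <- as.matrix(eq) * 255
    out[] <- round(pmin(255, pmax(0, out)))
    dimnames(out) <- dimnames(image)
    out
}

#' Window an HU-valued image to 8-bit
#'
#' Linearly maps intensities in the standard lung window [-1000, 400] HU to
#' 0-255, clipping outside the window. Used before CLAHE and quality
#' metrics when slices arrive in Hounsfield units.
#'
#' @param image numeric matrix in HU.
#' @param windowHU length-2 numeric, default \code{c(-1000, 400)}.
#' @return 8-bit matrix (values 0-255).
#' @export
windowToByte <- function(image, windowHU = c(-1000, 400)) {
    stopifnot(is.matrix(image), length(windowHU) == 2L,
              windowHU[1L] < windowHU[2L])
    x <- (image - windowHU[1L]) / diff(windowHU)
    x[] <- round(pmin(255, pmax(0, x * 255)))
    x
}

#' Pad and resize a slice to a square target
#'
#' Scales the image by \code{s = target / max(H, W)} (aspect ratio
#' preserved), centers it in a \code{target x target} canvas with symmetric
#' zero padding, and applies the same affine map to all nodule boxes (and
#' to the masks, nearest-neighbour). The affine parameters are stored in
#' the record so that \code{\link{invertPadResize}} recovers original-frame
#' boxes to within 0.5 px.
#'
#' @param record a \linkS4class{SliceRecord}.
#' @param target output side length in pixels, > 0.
#' @return The transformed record, with an attribute-like provenance entry
#'   in \code{metadata} columns of the nodule frame left untouched; the
#'   transform is returned in \code{attr(record, "padResize")}... see
#'   Details.
#' @details The transform is recorded as
#'   \code{list(scale, padX, padY, origW, origH)} on the returned object's
#'   \code{attr(, "padResize")}.
#' @export
padResize <- function(record, target) {
    stopifnot(is(record, "SliceRecord"), target > 0)
    img <- record@image
    H <- nrow(img); W <- ncol(img)
    s <- target / max(H, W)
    newH <- as.integer(round(H * s)); newW <- as.integer(round(W * s))
    padY <- (target - newH) %/% 2L
    padX <- (target - newW) %/% 2L
    scaleOne <- function(m, filter) {
        rs <- as.matrix(EBImage::resize(m, w = newH, h = newW,
                                        filter = filter))
        out <- matrix(0, target, target)
        out[padY + seq_len(newH), padX + seq_len(newW)] <- rs
        out
    }
    record@image <- if (s == 1 && newH == target && newW == target) img
                    else {
                        sc <- scaleOne(img, "bilinear")
                        sc[] <- round(pmin(255, pmax(0, sc)))
                        sc
                    }
    if (!is.null(record@mask))
        record@mask <- (scaleOne(record@mask, "none") > 0.5) * 1L
    if (!is.null(record@lungMask))
        record@lungMask <- (scaleOne(record@lungMask, "none") > 0.5) * 1L
    nd <- record@nodules
    if (nrow(nd)) {
        nd$xmin <- nd$xmin * s + padX; nd$xmax <- nd$xmax * s + padX
        nd$ymin <- nd$ymin * s + padY; nd$ymax <- nd$ymax * s + padY
        w <- nd$xmax - nd$xmin; h <- nd$ymax - nd$ymin
        nd$areaPx <- nd$areaPx * s^2
        nd$aspectRatio <- pmax(w / h, h / w)
        record@nodules <- nd
    }
    record@spacingMm <- record@spacingMm / s
    attr(record, "padResize") <- list(scale = s, padX = padX, padY = padY,
                                      origW = W, origH = H)
    record
}

#' Invert the pad-resize box transform
#'
#' Maps boxes from the padded/resized frame back to the original image
#' frame using the transform recorded by \code{\link{padResize}}.
#'
#' @param boxes data.frame with \code{xmin, ymin, xmax, ymax}.
#' @param transform the \code{list(scale, padX, padY, ...)} stored in
#'   \code{attr(record, "padResize")}.
#' @return Boxes in original-frame pixel coordinates.
#' @export
invertPadResize <- function(boxes, transform) {
    boxes <- asBoxFrame(boxes)
    s <- transform$scale
    boxes$xmin <- (boxes$xmin - transform$padX) / s
    boxes$xmax <- (boxes$xmax - transform$padX) / s
    boxes$ymin <- (boxes$ymin - transform$padY) / s
    boxes$ymax <- (boxes$ymax - transform$padY) / s
    boxes
}

#' Remove clinically irrelevant sub-3 mm nodules
#'
#' Drops every nodule whose diameter (\code{\link{noduleDiameterMm}}) is
#' strictly below \code{minDiameterMm}; the cutoff itself survives (a
#' 3.0 mm nodule is retained). Slices are never removed, only their
#' annotations, so a slice may become nodule-free. Idempotent.
#'
#' @param records a \linkS4class{SliceSet}.
#' @param minDiameterMm diameter cutoff in mm (default 3.0).
#' @return The filtered \code{SliceSet}.
#' @export
filterSmallNodules <- function(records, minDiameterMm = 3.0) {
    stopifnot(is(records, "SliceSet"))
    records@slices <- lapply(records@slices, function(rec) {
        if (!nrow(rec@nodules)) return(rec)
        d <- noduleDiameterMm(rec@nodules, rec@spacingMm)
        rec@nodules <- rec@nodules[d >= minDiameterMm, , drop = FALSE]
        rownames(rec@nodules) <- NULL
        rec
    })
    records
}

#' Nodule-oriented slice sampling
#'
#' Retains every nodule-bearing slice and an approximate
#' \code{1:ratio} complement of non-nodule slices (default 1:2), chosen
#' best-quality-first (tier high before medium before low, seeded random
#' order within a tier). If fewer non-nodule slices exist than the ratio
#' asks for, all are kept and a warning is issued.
#'
#' @param records a \linkS4class{SliceSet} with quality computed on every
#'   slice (see \code{\link{computeQualitySet}}).
#' @param ratio non-nodule slices retained per nodule slice.
#' @param seed integer seed for tie-breaking.
#' @return The sampled \code{SliceSet} (original slice order preserved).
#' @export
sampleSlices <- function(records, ratio = 2.0, seed = 1L) {
    stopifnot(is(records, "SliceSet"), ratio >= 0)
    tiers <- qualityTier(records)
    if (anyNA(tiers))
        stop("quality must be computed on all slices before sampling")
    nNod <- noduleCounts(records)
    pos <- which(nNod > 0L)
    neg <- which(nNod == 0L)
    target <- round(ratio * length(pos))
    if (length(neg) > target) {
        rank <- match(tiers[neg], c("high", "medium", "low"))
        ord <- withSeed(seed, order(rank, runif(length(neg))))
        keepNeg <- neg[ord[seq_len(target)]]
    } else {
        if (target > length(neg))
            warning(sprintf(paste0("only %d non-nodule slices available; ",
                                   "target was %d - keeping all"),
                            length(neg), target))
        keepNeg <- neg
    }
    records[sort(c(pos, keepNeg))]
}

# Seeded patient-level partition into length(fractions) groups, greedy by
# remaining slice-count deficit. Shared by all splitting operations.
partitionPatients <- function(patientOfSlice, fractions, seed) {
    stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0))
    patients <- unique(patientOfSlice)
    k <- length(fractions)
    if (length(patients) < k)
        stop(sprintf("need at least %d patients, got %d", k, length(patients)))
    counts <- table(patientOfSlice)[patients]
    ord <- withSeed(seed, sample.int(length(patients)))
    target <- fractions * length(patientOfSlice)
    filled <- numeric(k)
    assign <- integer(length(patients))
    for (i in ord) {
        g <- which.max(target - filled)  # largest remaining deficit
        assign[i] <- g
        filled[g] <- filled[g] + counts[[i]]
    }
    split(patients, assign)
}

#' Patient-level 80/10/10 split
#'
#' Partitions patients into train/validation/test so that no patient's
#' slices appear in more than one subset. Patients are shuffled with the
#' seed and assigned greedily by slice count to approach the target slice
#' fractions; realized slice fractions stay within a few percentage points
#' of the targets.
#'
#' @param records a \linkS4class{SliceSet}.
#' @param fractions length-3 numeric summing to 1 (default
#'   \code{c(0.8, 0.1, 0.1)}).
#' @param seed integer seed.
#' @return Named list \code{train}, \code{val}, \code{test} of patient-id
#'   character vectors.
#' @export
splitPatients <- function(records, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
    stopifnot(is(records, "SliceSet"), length(fractions) == 3L)
    parts <- partitionPatients(patientId(records), fractions, seed)
    list(train = as.character(parts[["1"]] %||% character(0)),
         val = as.character(parts[["2"]] %||% character(0)),
         test = as.character(parts[["3"]] %||% character(0)))
}

#' Teacher-scoring patient split
#'
#' Splits the training patients for model-driven difficulty scoring: 20%
#' of patients are held out solely for difficulty scoring; of the remaining
#' 80%, 90% trains the teacher and 10% validates it (72% / 8% / 20%
#' overall). Patient-disjoint and seed-deterministic; this split is
#' independent of the evaluation split.
#'
#' @param trainRecords a \linkS4class{SliceSet} (the training subset).
#' @param seed integer seed.
#' @return Named list \code{teacherTrain}, \code{teacherVal},
#'   \code{scoringHeldout} of patient-id vectors.
#' @export
teacherSplit <- function(trainRecords, seed = 1L) {
    stopifnot(is(trainRecords, "SliceSet"))
    pid <- patientId(trainRecords)
    first <- partitionPatients(pid, c(0.8, 0.2), seed)
    heldout <- as.character(first[["2"]] %||% character(0))
    rest <- pid[pid %in% as.character(first[["1"]])]
    second <- partitionPatients(rest, c(0.9, 0.1), deriveSeed(seed, 1L))
    list(teacherTrain = as.character(second[["1"]] %||% character(0)),
         teacherVal = as.character(second[["2"]] %||% character(0)),
         scoringHeldout = heldout)
}

#' Proportional patient-level training subsets
#'
#' Builds \code{nFolds} patient-level subsets each retaining approximately
#' \code{fraction} of the training slices (within a few percent for
#' reasonably granular patients), for data-efficiency experiments at
#' fractions such as 1/2, 1/5 and 1/10. Folds differ by seeded resampling
#' of the patient order; no patient is ever split across the inclusion
#' boundary.
#'
#' @param trainRecords a \linkS4class{SliceSet}.
#' @param fraction target fraction of slices in (0, 1].
#' @param nFolds number of folds.
#' @param seed integer base seed (fold f uses a seed derived from it).
#' @return List of \code{nFolds} \code{SliceSet} subsets.
#' @export
proportionalSubsets <- function(trainRecords, fraction, nFolds = 3L,
                                seed = 1L) {
    stopifnot(is(trainRecords, "SliceSet"), fraction > 0, fraction <= 1)
    if (fraction == 1)
        return(replicate(nFolds, trainRecords, simplify = FALSE))
    pid <- patientId(trainRecords)
    patients <- unique(pid)
    counts <- table(pid)[patients]
    target <- fraction * length(pid)
    lapply(seq_len(nFolds), function(f) {
        ord <- withSeed(deriveSeed(seed, f), sample.int(length(patients)))
        cum <- 0
        chosen <- character(0)
        for (i in ord) {
            ci <- counts[[i]]
            if (abs(cum + ci - target) <= abs(cum - target)) {
                chosen <- c(chosen, patients[i])
                cum <- cum + ci
            }
            if (cum >= target) break
        }
        trainRecords[which(pid %in% chosen)]
    })
}

#' Fixed-size patient-level training subset
#'
#' Appends whole patients in seeded random order until the cumulative slice
#' count first reaches or exceeds \code{nSlices}; the boundary patient is
#' included whole. Used for fixed-budget data-efficiency experiments
#' (e.g. 5000/10000/20000/40000 slices) with the conventional fixed seed 42.
#'
#' @param trainRecords a \linkS4class{SliceSet}.
#' @param nSlices target slice count, at most the total available.
#' @param seed integer seed (default 42).
#' @return A \code{SliceSet} subset.
#' @export
fixedSizeSubset <- function(trainRecords, nSlices, seed = 42L) {
    stopifnot(is(trainRecords, "SliceSet"))
    pid <- patientId(trainRecords)
    if (nSlices > length(pid))
        stop(sprintf("requested %d slices but only %d available",
                     nSlices, length(pid)))
    patients <- unique(pid)
    counts <- table(pid)[patients]
    ord <- withSeed(seed, sample.int(length(patients)))
    cum <- cumsum(as.numeric(counts[ord]))
    nTake <- which(cum >= nSlices)[1L]
    chosen <- patients[ord[seq_len(nTake)]]
    trainRecords[which(pid %in% chosen)]
}
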