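#' Create a synthetic dataset specification
#'
#' Builds a validated \linkS4class{FixtureSpec} for the CT-like fixture
#' generator. The defaults emulate the statistical shape of a heterogeneous
#' low-dose chest-CT slice collection: most slices carry 0-1 nodules with a
#' tail up to 5, nodule areas span the sub-400 px to >1000 px difficulty
#' bands, aspect ratios reach beyond the 2:1 irregularity cutoff, and blur
#' and noise amplitude ranges straddle the Laplacian-variance 500 and
#' contrast 30 quality thresholds so that all three quality tiers occur.
#'
#' @param nPatients number of synthetic patients.
#' @param slicesPerPatient slices generated per patient.
#' @param noduleCountDist probability vector over nodule counts 0..5
#'   (named "0".."5", or unnamed length 6).
#' @param areaRangePx nodule area interval in pixels squared.
#' @param aspectRatioRange ellipse aspect-ratio interval (>= 1).
#' @param blurSigmaRange Gaussian blur sigma interval in pixels; 0 means a
#'   sharp slice.
#' @param contrastRange lung-region noise amplitude interval in 8-bit
#'   intensity units (drives the measured contrast metric).
#' @param imageSize square image side in pixels.
#' @param spacingMm in-plane pixel spacing in mm/pixel; 0.7 mm is a typical
#'   chest-CT value and makes the <3 mm nodule filter exercisable.
#' @param seed integer seed; the generator is fully deterministic given the
#'   spec.
#' @return A \linkS4class{FixtureSpec}.
#' @export
fixtureSpec <- function(nPatients = 30L,
                        slicesPerPatient = 10L,
                        noduleCountDist = c("0" = 0.40, "1" = 0.30,
                                            "2" = 0.15, "3" = 0.08,
                                            "4" = 0.04, "5" = 0.03),
                        areaRangePx = c(200, 2000),
                        aspectRatioRange = c(1, 3),
                        blurSigmaRange = c(0, 3),
                        contrastRange = c(8, 60),
                        imageSize = 192L,
                        spacingMm = 0.7,
                        seed = 1L) {
    if (is.null(names(noduleCountDist))) {
        stopifnot(length(noduleCountDist) == 6L)
        names(noduleCountDist) <- as.character(0:5)
    }
    noduleCountDist <- noduleCountDist[as.character(0:5)]
    noduleCountDist[is.na(noduleCountDist)] <- 0
    names(noduleCountDist) <- as.character(0:5)
    new("FixtureSpec",
        nPatients = as.integer(nPatients),
        slicesPerPatient = as.integer(slicesPerPatient),
        noduleCountDist = noduleCountDist,
        areaRangePx = as.numeric(areaRangePx),
        aspectRatioRange = as.numeric(aspectRatioRange),
        blurSigmaRange = as.numeric(blurSigmaRange),
        contrastRange = as.numeric(contrastRange),
        imageSize = as.integer(imageSize),
        spacingMm = as.numeric(spacingMm),
        seed = as.integer(seed))
}

#' Generate a synthetic CT-like slice dataset
#'
#' Produces a \linkS4class{SliceSet} of 8-bit grayscale slices grouped into
#' synthetic patients. Each slice contains a circular low-intensity "lung"
#' region on a brighter body background, a smoothed random field plus fine
#' noise whose amplitude sets the measured contrast, 0-5 bright elliptical
#' nodules (filled, axis-aligned, mutually non-adjacent; when random
#' placement cannot fit the drawn count without overlap, the slice keeps
#' the nodules that fit), and an optional
#' global Gaussian blur that degrades the Laplacian-variance sharpness
#' metric. Per-nodule annotations (tight box, exact mask foreground count,
#' box aspect ratio) are derived from the rasterized masks, so the recorded
#' area always equals the mask pixel count.
#'
#' The output is deterministic given the spec (including its seed): two
#' calls yield byte-identical images and masks.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param patientPrefix prefix for generated patient ids (useful when
#'   combining several generated sets).
#' @return A \linkS4class{SliceSet} with masks and lung masks attached.
#' @examples
#' ss <- generateDataset(fixtureSpec(nPatients = 2L, slicesPerPatient = 2L,
#'                                   imageSize = 96L, seed = 7L))
#' ss
#' @export
generateDataset <- function(spec, patientPrefix = "P") {
    stopifnot(is(spec, "FixtureSpec"))
    validObject(spec)
    S <- spec@imageSize
    lungR <- 0.42 * S
    minAxis <- minSemiAxis(spec)
    if (minAxis + 4 > lungR)
        stop(sprintf(paste0("infeasible geometry: even the smallest ",
                            "configured nodule (semi-axis %.1f px) cannot ",
                            "fit inside a lung region of radius %.1f px ",
                            "(image size %d)"),
                     minAxis, lungR, S))
    withSeed(spec@seed, {
        slices <- vector("list", spec@nPatients * spec@slicesPerPatient)
        k <- 0L
        for (p in seq_len(spec@nPatients)) {
            pid <- sprintf("%s%03d", patientPrefix, p)
            for (s in seq_len(spec@slicesPerPatient)) {
                k <- k + 1L
                slices[[k]] <- generateSlice(
                    spec, sprintf("%s_s%03d", pid, s), pid, lungR)
            }
        }
        new("SliceSet", slices = slices)
    })
}

# Semi-major axis of the smallest configurable nodule (smallest area at
# the least elongated aspect ratio). If even this cannot fit, the spec is
# geometrically infeasible; larger draws that do not fit are simply
# resampled during placement.
minSemiAxis <- function(spec) {
    A <- spec@areaRangePx[1L]
    r <- spec@aspectRatioRange[1L]
    max(sqrt(A * r / pi), 0.8 * r)
}

# One slice: background + lung disk + noise + nodules, then blur.
generateSlice <- function(spec, sid, pid, lungR) {
    S <- spec@imageSize
    nNod <- sample(0:5, 1L, prob = spec@noduleCountDist)
    contrastAmp <- runif(1L, spec@contrastRange[1L], spec@contrastRange[2L])
    blurSigma <- runif(1L, spec@blurSigmaRange[1L], spec@blurSigmaRange[2L])

    cx <- (S + 1) / 2
    rr <- row(matrix(0, S, S)) - cx
    cc <- col(matrix(0, S, S)) - cx
    lung <- (rr^2 + cc^2) <= lungR^2

    # coarse smoothed field for intensity heterogeneity
    g <- max(4L, S %/% 16L)
    coarse <- matrix(rnorm(g * g), g, g)
    field <- as.matrix(EBImage::resize(coarse, w = S, h = S))
    img <- ifelse(lung, 70, 185) + field * contrastAmp * 0.4 +
        rnorm(S * S, sd = contrastAmp * 0.9)

    mask <- matrix(0L, S, S)
    nod <- emptyNoduleFrame()
    placed <- 0L
    tries <- 0L
    while (placed < nNod) {
        tries <- tries + 1L
        if (tries > 60L * max(nNod, 1L)) break  # crowded: keep what fits
        area <- runif(1L, spec@areaRangePx[1L], spec@areaRangePx[2L])
        ar <- runif(1L, spec@aspectRatioRange[1L], spec@aspectRatioRange[2L])
        b <- max(0.8, sqrt(area / (pi * ar)))
        a <- ar * b
        if (runif(1L) < 0.5) { tmp <- a; a <- b; b <- tmp }  # orientation
        margin <- max(a, b) + 2
        if (margin >= lungR) next
        ang <- runif(1L, 0, 2 * pi)
        rad <- sqrt(runif(1L)) * (lungR - margin)
        ny <- cx + rad * sin(ang)
        nx <- cx + rad * cos(ang)
        ell <- ((cc + cx - nx) / a)^2 + ((rr + cx - ny) / b)^2 <= 1
        if (!any(ell)) next
        # keep nodules disjoint and non-adjacent so components stay separate
        if (any(mask[dilate1(ell)] == 1L)) next
        mask[ell] <- 1L
        img[ell] <- 150 + rnorm(sum(ell), sd = 4)
        placed <- placed + 1L
    }

    if (blurSigma > 0.05)
        img <- as.matrix(EBImage::gblur(img, sigma = blurSigma))
    img[] <- round(pmin(255, pmax(0, img)))

    new("SliceRecord", sliceId = sid, patientId = pid, image = img,
        spacingMm = spec@spacingMm,
        nodules = nodulesFromMask(mask),
        mask = mask, lungMask = lung * 1L, quality = NULL)
}

# binary dilation by one pixel (8-neighbourhood), used to keep generated
# nodules non-adjacent
dilate1 <- function(m) {
    nr <- nrow(m); nc <- ncol(m)
    out <- m
    out[-1, ] <- out[-1, ] | m[-nr, ]
    out[-nr, ] <- out[-nr, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -nc]
    out[, -nc] <- out[, -nc] | m[, -1]
    out[-1, -1] <- out[-1, -1] | m[-nr, -nc]
    out[-nr, -nc] <- out[-nr, -nc] | m[-1, -1]
    out[-1, -nc] <- out[-1, -nc] | m[-nr, -1]
    out[-nr, -1] <- out[-nr, -1] | m[-1, -nc]
    out
}

#' Simulate a teacher detector
#'
#' Emits one \linkS4class{DetectionSummary} per slice, standing in for an
#' external teacher detector. \code{qualityOfTeacher} is the single quality
#' knob: each ground-truth nodule is detected with probability equal to it,
#' detected boxes are jittered with noise proportional to (1 - quality),
#' per-box confidence is drawn from a Beta distribution with mean equal to
#' the quality (degenerate at 1), and spurious boxes appear at Poisson rate
#' 0.5 (1 - quality). Five pre-NMS candidate scores with amplitude
#' (1 - quality) are always emitted, so the no-box confidence surrogate
#' (1 minus the mean top-5 pre-NMS score) is defined for every slice.
#'
#' At \code{qualityOfTeacher = 1} the teacher reproduces the ground truth
#' exactly with confidence 1.0 and zero pre-NMS scores.
#'
#' @param records a \linkS4class{SliceSet} carrying ground-truth boxes.
#' @param qualityOfTeacher scalar in [0, 1].
#' @param seed integer seed; output is deterministic given it.
#' @return List of \linkS4class{DetectionSummary}, one per slice.
#' @export
simulateTeacher <- function(records, qualityOfTeacher = 0.7, seed = 1L) {
    stopifnot(is(records, "SliceSet"),
              qualityOfTeacher >= 0, qualityOfTeacher <= 1)
    q <- qualityOfTeacher
    withSeed(seed, lapply(records@slices, function(rec) {
        S <- nrow(rec@image)
        gt <- rec@nodules
        det <- if (nrow(gt)) runif(nrow(gt)) < q else logical(0)
        boxes <- gt[det, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE]
        if (nrow(boxes) && q < 1) {
            jit <- matrix(rnorm(4L * nrow(boxes), sd = 3 * (1 - q)),
                          ncol = 4L)
            boxes$xmin <- pmax(0, pmin(boxes$xmin + jit[, 1L], S - 1))
            boxes$ymin <- pmax(0, pmin(boxes$ymin + jit[, 2L], S - 1))
            boxes$xmax <- pmax(boxes$xmin + 1, pmin(boxes$xmax + jit[, 3L], S))
            boxes$ymax <- pmax(boxes$ymin + 1, pmin(boxes$ymax + jit[, 4L], S))
        }
        conf <- if (q >= 1) rep(1, nrow(boxes)) else betaMean(nrow(boxes), q)
        nFp <- rpois(1L, 0.5 * (1 - q))
        if (nFp > 0L) {
            w <- runif(nFp, 8, 30); h <- runif(nFp, 8, 30)
            x0 <- runif(nFp, 0, S - w); y0 <- runif(nFp, 0, S - h)
            boxes <- rbind(boxes, data.frame(xmin = x0, ymin = y0,
                                             xmax = x0 + w, ymax = y0 + h))
            conf <- c(conf, betaMean(nFp, min(0.95, 0.1 + 0.4 * (1 - q))))
        }
        pre <- sort((1 - q) * runif(5L), decreasing = TRUE)
        rownames(boxes) <- NULL
        new("DetectionSummary", sliceId = rec@sliceId,
            boxes = as.data.frame(boxes), confidences = as.numeric(conf),
            preNmsScores = pre, nGt = nrow(gt))
    }))
}

# Beta draw with given mean (concentration 12), degenerate at the endpoints.
betaMean <- function(n, m, k = 12) {
    if (n == 0L) return(numeric(0))
    if (m <= 0) return(rep(0, n))
    if (m >= 1) return(rep(1, n))
    rbeta(n, m * k, (1 - m) * k)
}
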