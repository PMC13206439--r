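# Lightweight record construction for tests that do not need real images.

qualityFromTier <- function(tier) {
    m <- switch(tier,
        high = c(lap = 800, con = 45),
        medium = c(lap = 300, con = 45),
        low = c(lap = 50, con = 5))
    new("QualityMetrics", lungCoverage = 1,
        intensityHeterogeneity = unname(m["con"]),
        laplacianVariance = unname(m["lap"]),
        contrast = unname(m["con"]), qualityTier = tier)
}

# A minimal SliceRecord with prescribed nodule areas / aspect ratios and
# quality tier; boxes are synthesized (geometry is irrelevant for the
# difficulty factors, which read areaPx and aspectRatio).
makeRecord <- function(sliceId, patientId = "P1", areas = numeric(0),
                       ars = rep(1.2, length(areas)), tier = "high",
                       spacingMm = 0.7, imageSize = 8L) {
    n <- length(areas)
    nod <- if (n == 0) {
        data.frame(xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
                   ymax = numeric(0), areaPx = numeric(0),
                   aspectRatio = numeric(0))
    } else {
        data.frame(xmin = rep(0, n), ymin = rep(0, n),
                   xmax = rep(4, n), ymax = rep(4, n),
                   areaPx = areas, aspectRatio = ars)
    }
    new("SliceRecord", sliceId = sliceId, patientId = patientId,
        image = matrix(0, imageSize, imageSize), spacingMm = spacingMm,
        nodules = nod, mask = NULL, lungMask = NULL,
        quality = qualityFromTier(tier))
}

# A SliceSet of trivial records: `counts[p]` slices for patient p.
makePatientSet <- function(counts, positive = rep(FALSE, sum(counts)),
                           tiers = rep("high", sum(counts))) {
    k <- 0L
    slices <- list()
    for (p in seq_along(counts)) {
        for (s in seq_len(counts[p])) {
            k <- k + 1L
            slices[[k]] <- makeRecord(
                sprintf("p%03d_s%03d", p, s), sprintf("p%03d", p),
                areas = if (positive[k]) 500 else numeric(0),
                tier = tiers[k])
        }
    }
    new("SliceSet", slices = slices)
}

# One small generated dataset shared across test files (computed lazily).
.testCache <- new.env(parent = emptyenv())
tinySet <- function() {
    if (is.null(.testCache$tiny)) {
        .testCache$tiny <- computeQualitySet(generateDataset(
            fixtureSpec(nPatients = 6L, slicesPerPatient = 4L,
                        imageSize = 128L, seed = 11L)))
    }
    .testCache$tiny
}
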