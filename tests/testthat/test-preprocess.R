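test_that("quality metrics behave on degenerate and crafted inputs", {
    rec <- makeRecord("flat", imageSize = 32L)
    rec@quality <- NULL
    out <- computeQuality(rec)
    q <- qualityMetrics(out)
    expect_equal(q@laplacianVariance, 0)
    expect_equal(q@contrast, 0)
    expect_identical(q@qualityTier, "low")

    # lung coverage is the mask fraction
    lm <- matrix(0L, 32, 32); lm[1:16, 1:16] <- 1L
    out <- computeQuality(rec, lungMask = lm)
    expect_equal(qualityMetrics(out)@lungCoverage, 0.25)
})

test_that("a sharp, high-contrast fixture slice scores tier high", {
    spec <- fixtureSpec(nPatients = 1L, slicesPerPatient = 2L,
                        blurSigmaRange = c(0, 0),
                        contrastRange = c(55, 60),
                        imageSize = 96L, seed = 4L)
    ss <- computeQualitySet(generateDataset(spec))
    for (rec in ss@slices) {
        q <- qualityMetrics(rec)
        expect_gt(q@laplacianVariance, 500)
        expect_gt(q@contrast, 30)
        expect_identical(q@qualityTier, "high")
    }
})

test_that("tier follows the stated thresholds on generated slices", {
    ss <- tinySet()
    for (rec in ss@slices) {
        q <- qualityMetrics(rec)
        want <- if (q@laplacianVariance > 500 && q@contrast > 30) "high"
                else if (q@laplacianVariance <= 150 || q@contrast <= 15) "low"
                else "medium"
        expect_identical(q@qualityTier, want)
    }
})

test_that("CLAHE preserves shape, leaves constants alone, raises contrast", {
    flat <- matrix(120, 64, 64)
    expect_identical(applyClahe(flat), flat)

    spec <- fixtureSpec(nPatients = 1L, slicesPerPatient = 3L,
                        noduleCountDist = c(1, 0, 0, 0, 0, 0),
                        blurSigmaRange = c(0, 0), contrastRange = c(8, 10),
                        imageSize = 96L, seed = 6L)
    ss <- generateDataset(spec)
    for (rec in ss@slices) {
        eq <- applyClahe(rec)
        expect_identical(dim(eq@image), dim(rec@image))
        expect_true(all(eq@image >= 0 & eq@image <= 255))
        # the lung-region contrast metric strictly increases
        expect_gt(qualityMetrics(computeQuality(eq))@contrast,
                  qualityMetrics(computeQuality(rec))@contrast)
        twice <- applyClahe(eq@image)
        expect_identical(dim(twice), dim(eq@image))
        expect_true(all(twice >= 0 & twice <= 255))
    }
})

test_that("HU windowing maps the lung window to 8-bit", {
    hu <- matrix(c(-1200, -1000, -300, 400, 500), 1)
    b <- windowToByte(hu)
    expect_equal(b[1, ], c(0, 0, 128, 255, 255))
})

test_that("pad-resize scales, centers and transforms boxes invertibly", {
    # square input at target size: identity
    rec <- tinySet()[[1]]
    out <- padResize(rec, nrow(rec@image))
    expect_identical(out@image, rec@image)
    expect_equal(out@nodules, rec@nodules)

    # 200x400 (rows x cols) to 512: scale 1.28, vertical padding 128
    wide <- makeRecord("wide", areas = 100, imageSize = 8L)
    wide@image <- matrix(100, 200, 400)
    wide@nodules <- data.frame(xmin = 0, ymin = 0, xmax = 400, ymax = 200,
                               areaPx = 100, aspectRatio = 2)
    out <- padResize(wide, 512L)
    tr <- attr(out, "padResize")
    expect_equal(tr$scale, 1.28)
    expect_identical(dim(out@image), c(512L, 512L))
    expect_true(all(out@image[129:384, ] > 0))
    expect_true(all(out@image[1:128, ] == 0) && all(out@image[385:512, ] == 0))
    expect_equal(unlist(out@nodules[, c("xmin", "ymin", "xmax", "ymax")]),
                 c(0, 128, 512, 384), ignore_attr = TRUE)

    # random box round-trip through the affine map
    set.seed(12)
    x0 <- runif(50, 0, 350); y0 <- runif(50, 0, 150)
    boxes <- data.frame(xmin = x0, ymin = y0, xmax = x0 + runif(50, 1, 40),
                        ymax = y0 + runif(50, 1, 40))
    fwd <- boxes
    fwd$xmin <- fwd$xmin * tr$scale + tr$padX
    fwd$xmax <- fwd$xmax * tr$scale + tr$padX
    fwd$ymin <- fwd$ymin * tr$scale + tr$padY
    fwd$ymax <- fwd$ymax * tr$scale + tr$padY
    back <- invertPadResize(fwd, tr)
    expect_lt(max(abs(as.matrix(back) - as.matrix(boxes))), 0.5)
})

test_that("sub-3 mm nodules are removed strictly and idempotently", {
    recs <- new("SliceSet", slices = list(
        makeRecord("a", areas = c(100, 200)),  # boxes 4x4 px at 0.7 mm -> 2.8 mm
        makeRecord("b", areas = numeric(0))))
    # give slice a one large nodule too
    recs@slices[[1]]@nodules$xmax <- c(4, 10)
    recs@slices[[1]]@nodules$ymax <- c(4, 10)
    f1 <- filterSmallNodules(recs)
    expect_identical(noduleCounts(f1), c(1L, 0L))  # 2.8 mm removed, 7 mm kept
    expect_identical(noduleCounts(filterSmallNodules(f1)),
                     noduleCounts(f1))             # idempotent

    # exactly 3.0 mm survives (strict <)
    rec3 <- makeRecord("c", areas = 9, spacingMm = 1.0)
    rec3@nodules$xmax <- 3; rec3@nodules$ymax <- 3
    expect_identical(noduleCounts(filterSmallNodules(
        new("SliceSet", slices = list(rec3)))), 1L)
})

test_that("slice sampling retains positives and a 1:2 complement of negatives", {
    pos <- lapply(1:100, function(i) makeRecord(sprintf("pos%03d", i),
                                                sprintf("PP%03d", i),
                                                areas = 500))
    neg <- lapply(1:1000, function(i) makeRecord(sprintf("neg%04d", i),
                                                 sprintf("PN%03d", i %% 100),
                                                 tier = c("high", "medium",
                                                          "low")[1 + i %% 3]))
    ss <- new("SliceSet", slices = c(pos, neg))
    out <- sampleSlices(ss, ratio = 2.0, seed = 1L)
    cnt <- noduleCounts(out)
    expect_identical(sum(cnt > 0), 100L)
    expect_identical(sum(cnt == 0), 200L)

    # too few negatives: all kept, warning
    small <- new("SliceSet", slices = c(pos, neg[1:50]))
    expect_warning(out2 <- sampleSlices(small, 2.0, 1L), "keeping all")
    expect_identical(length(out2), 150L)

    # no positives: no negatives retained
    onlyNeg <- new("SliceSet", slices = neg[1:20])
    expect_identical(length(sampleSlices(onlyNeg, 2.0, 1L)), 0L)
})

test_that("negative selection is best-quality-first", {
    pos <- lapply(1:2, function(i) makeRecord(sprintf("p%d", i), areas = 500))
    neg <- c(lapply(1:3, function(i) makeRecord(sprintf("h%d", i), tier = "high")),
             lapply(1:7, function(i) makeRecord(sprintf("l%d", i), tier = "low")))
    out <- sampleSlices(new("SliceSet", slices = c(pos, neg)), 2.0, seed = 3L)
    kept <- sliceId(out)
    expect_true(all(c("h1", "h2", "h3") %in% kept))
    expect_identical(sum(startsWith(kept, "l")), 1L)
})

test_that("patient split is disjoint, deterministic and near target", {
    ss <- makePatientSet(rep(5L, 10L))
    sp <- splitPatients(ss, seed = 2L)
    expect_identical(lengths(sp), c(train = 8L, val = 1L, test = 1L))
    expect_identical(sp, splitPatients(ss, seed = 2L))
    allP <- unique(patientId(ss))
    expect_setequal(unlist(sp), allP)
    expect_identical(anyDuplicated(unlist(sp)), 0L)

    # uneven patients: slice fractions within 3 percentage points
    set.seed(8)
    counts <- sample(3:40, 100, replace = TRUE)
    big <- makePatientSet(counts)
    sp <- splitPatients(big, seed = 5L)
    pid <- patientId(big)
    frac <- vapply(sp, function(p) mean(pid %in% p), numeric(1))
    expect_true(all(abs(frac - c(0.8, 0.1, 0.1)) <= 0.03))

    expect_error(splitPatients(makePatientSet(c(4L, 4L))), "at least 3")
})

test_that("teacher split yields 72/8/20 disjoint patients", {
    ss <- makePatientSet(rep(4L, 100L))
    ts <- teacherSplit(ss, seed = 3L)
    expect_identical(lengths(ts), c(teacherTrain = 72L, teacherVal = 8L,
                                    scoringHeldout = 20L))
    expect_identical(anyDuplicated(unlist(ts)), 0L)
    expect_setequal(unlist(ts), unique(patientId(ss)))
    expect_identical(ts, teacherSplit(ss, seed = 3L))
})

test_that("proportional subsets are patient-atomic and near-fractional", {
    ss <- makePatientSet(rep(10L, 100L))  # 1000 slices
    expect_identical(length(proportionalSubsets(ss, 1, 2L, 1L)[[1]]), 1000L)
    folds <- proportionalSubsets(ss, 1 / 2, nFolds = 3L, seed = 7L)
    for (f in folds) {
        expect_true(length(f) >= 475 && length(f) <= 525)
        tab <- table(patientId(f))
        expect_true(all(tab == 10L))  # whole patients only
    }
    expect_false(identical(sort(sliceId(folds[[1]])),
                           sort(sliceId(folds[[2]]))))
})

test_that("fixed-size subsets follow the sequential stop rule", {
    ss <- makePatientSet(c(3L, 3L, 3L))
    sub <- fixedSizeSubset(ss, 5L, seed = 42L)
    expect_identical(length(sub), 6L)                 # boundary patient whole
    expect_identical(length(unique(patientId(sub))), 2L)
    expect_identical(sliceId(fixedSizeSubset(ss, 5L, seed = 42L)),
                     sliceId(sub))
    expect_identical(length(fixedSizeSubset(ss, 9L)), 9L)
    expect_error(fixedSizeSubset(ss, 10L), "only 9")
})
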