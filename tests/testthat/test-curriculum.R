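scoreFrame <- function(n = 40L, seed = 15L) {
    set.seed(seed)
    data.frame(
        sliceId = sprintf("s%03d", seq_len(n)),
        cManual = runif(n, 2, 11),
        cDet = runif(n, 0.5, 8),
        isPositive = runif(n) < 0.6,
        qualityTier = sample(c("high", "medium", "low"), n, replace = TRUE))
}

withTiers <- function(sc, a) {
    sc$tier <- assignTier(fuseDifficulty(sc$cManual, sc$cDet, a))
    sc
}

test_that("fusion is the convex combination with guarded coefficient", {
    expect_equal(fuseDifficulty(5, 2, a = 1), 5)
    expect_equal(fuseDifficulty(5, 2, a = 0), 2)
    expect_equal(fuseDifficulty(3.0, 1.3, a = 0.2), 1.64)
    expect_error(fuseDifficulty(5, 2, a = -0.1), "\\[0, 1\\]")
    expect_error(fuseDifficulty(5, 2, a = 1.1), "\\[0, 1\\]")
    expect_error(fuseDifficulty(5, 2, a = NA), "\\[0, 1\\]")

    set.seed(41)
    cm <- runif(10000, 2, 11); cd <- runif(10000, 0.5, 8)
    for (a in c(0, 0.2, 0.5, 1)) {
        ch <- fuseDifficulty(cm, cd, a)
        expect_true(all(ch >= pmin(cm, cd) - 1e-12 &
                        ch <= pmax(cm, cd) + 1e-12))
    }
})

test_that("tier thresholds sit exactly at 3 and 6", {
    expect_identical(assignTier(c(3.0, 6.0, 6.01, 2.99, 3.01)),
                     c("simple", "medium", "complex", "simple", "medium"))
    set.seed(5)
    tiers <- assignTier(runif(500, 0, 12))
    expect_true(all(tiers %in% c("simple", "medium", "complex")))
})

test_that("stage configs carry the printed hyperparameters", {
    cfgs <- defaultStageConfigs()
    expect_identical(vapply(cfgs, slot, integer(1), "inputResolution"),
                     c(512L, 640L, 768L))
    expect_identical(vapply(cfgs, slot, integer(1), "epochs"),
                     c(50L, 100L, 100L))
    expect_equal(vapply(cfgs, slot, numeric(1), "learningRate"),
                 c(0.003, 0.002, 0.001))
    expect_equal(lapply(cfgs, slot, "lossWeights"),
                 list(c(box = 2.0, cls = 4.0, dfl = 0.1),
                      c(box = 5.0, cls = 2.0, dfl = 0.5),
                      c(box = 7.0, cls = 1.5, dfl = 1.0)))
    expect_equal(lapply(cfgs, slot, "augmentation"),
                 list(c(rotationDeg = 3, translationFrac = 0.05, scaleFrac = 0.10),
                      c(rotationDeg = 8, translationFrac = 0.10, scaleFrac = 0.20),
                      c(rotationDeg = 12, translationFrac = 0.15, scaleFrac = 0.30)))
    # included tiers strictly grow with the stage
    expect_true(all(cfgs[[1]]@includedTiers %in% cfgs[[2]]@includedTiers))
    expect_true(all(cfgs[[2]]@includedTiers %in% cfgs[[3]]@includedTiers))
})

test_that("curriculum stages are nested, cumulative and complete", {
    sc <- withTiers(scoreFrame(), a = 0.2)
    man <- buildCurriculum(sc)
    s <- man@stages
    expect_true(all(s[[1]] %in% s[[2]]))
    expect_true(all(s[[2]] %in% s[[3]]))
    expect_setequal(s[[3]], sc$sliceId)
    # stage membership honors the inclusion rules
    pos1 <- intersect(s[[1]], sc$sliceId[sc$isPositive])
    expect_true(all(sc$tier[match(pos1, sc$sliceId)] == "simple"))
    neg1 <- intersect(s[[1]], sc$sliceId[!sc$isPositive])
    expect_true(all(sc$qualityTier[match(neg1, sc$sliceId)] == "high"))

    # degenerate: all simple -> all positives in every stage
    allSimple <- sc; allSimple$tier <- "simple"
    m2 <- buildCurriculum(allSimple)
    posIds <- sc$sliceId[sc$isPositive]
    for (k in 1:3)
        expect_true(all(posIds %in% m2@stages[[k]]))

    noSimple <- sc; noSimple$tier <- "complex"
    expect_warning(buildCurriculum(noSimple), "negatives only")
})

test_that("baseline configuration carries the printed values", {
    cfg <- baselineConfig()
    expect_identical(cfg$inputResolution, 640L)
    expect_identical(cfg$batchSize, 32L)
    expect_identical(cfg$maxEpochs, 500L)
    expect_equal(cfg$learningRate, 1e-4)
    expect_equal(cfg$momentum, 0.937)
    expect_equal(cfg$weightDecay, 5e-4)
    expect_identical(cfg$patience, 30L)
    expect_equal(cfg$lossWeights, c(box = 5.0, cls = 2.0, dfl = 0.3))
    expect_equal(cfg$confThreshold, 0.1)
    expect_equal(cfg$iouThreshold, 0.5)
})

test_that("mixing sweep endpoints reproduce the single-source curricula", {
    sc <- scoreFrame()
    sw <- sweepMixing(sc, aGrid = c(0, 1, 1, 0.2))
    expect_identical(names(sw$manifests), c("0", "0.2", "1"))

    manualOnly <- buildCurriculum(withTiers(sc, 1))
    detOnly <- buildCurriculum(withTiers(sc, 0))
    expect_identical(sw$manifests[["1"]]@stages, manualOnly@stages)
    expect_identical(sw$manifests[["0"]]@stages, detOnly@stages)

    # constant scores: identical manifests for every a
    const <- sc; const$cDet <- const$cManual
    swc <- sweepMixing(const, aGrid = c(0, 0.5, 1))
    expect_identical(swc$manifests[["0"]]@stages,
                     swc$manifests[["1"]]@stages)
    expect_identical(swc$manifests[["0.5"]]@stages,
                     swc$manifests[["1"]]@stages)
})

test_that("manifest YAML round-trips stage lists and configs", {
    sc <- withTiers(scoreFrame(), 0.2)
    man <- buildCurriculum(sc, provenance = list(a = 0.2, seed = 7L))
    tmp <- withr::local_tempfile(fileext = ".yaml")
    writeCurriculumManifest(man, tmp)
    back <- readCurriculumManifest(tmp)
    expect_identical(back@stages, man@stages)
    expect_equal(lapply(back@configs, slot, "lossWeights"),
                 lapply(man@configs, slot, "lossWeights"))
    expect_equal(lapply(back@configs, slot, "augmentation"),
                 lapply(man@configs, slot, "augmentation"))
    expect_identical(back@provenance$a, 0.2)
})
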