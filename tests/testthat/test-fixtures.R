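test_that("generation is byte-identical for identical spec and seed", {
    spec <- fixtureSpec(nPatients = 3L, slicesPerPatient = 2L,
                        imageSize = 96L, seed = 42L)
    a <- generateDataset(spec)
    b <- generateDataset(spec)
    expect_identical(lapply(a@slices, slot, "image"),
                     lapply(b@slices, slot, "image"))
    expect_identical(lapply(a@slices, slot, "mask"),
                     lapply(b@slices, slot, "mask"))
    expect_identical(lapply(a@slices, slot, "nodules"),
                     lapply(b@slices, slot, "nodules"))
})

test_that("a degenerate nodule-count distribution yields only empty masks", {
    spec <- fixtureSpec(nPatients = 2L, slicesPerPatient = 3L,
                        noduleCountDist = c(1, 0, 0, 0, 0, 0),
                        imageSize = 96L, seed = 9L)
    ss <- generateDataset(spec)
    expect_true(all(noduleCounts(ss) == 0L))
    expect_true(all(vapply(ss@slices, function(s) sum(s@mask) == 0,
                           logical(1))))
})

test_that("nodule areas are controlled to rasterization tolerance", {
    spec <- fixtureSpec(nPatients = 4L, slicesPerPatient = 3L,
                        noduleCountDist = c(0, 1, 0, 0, 0, 0),
                        areaRangePx = c(400, 400),
                        aspectRatioRange = c(1, 1),
                        imageSize = 96L, seed = 5L)
    ss <- generateDataset(spec)
    areas <- unlist(lapply(ss@slices, function(s) s@nodules$areaPx))
    expect_length(areas, length(ss))
    expect_true(all(abs(areas - 400) / 400 <= 0.05))
    # recorded area equals the mask foreground count
    expect_equal(areas, vapply(ss@slices, function(s) sum(s@mask),
                               numeric(1)))
})

test_that("derived boxes tightly contain all mask foreground", {
    ss <- tinySet()
    for (rec in ss@slices) {
        boxes <- maskToBoxes(rec@mask)
        expect_identical(nrow(boxes), nrow(rec@nodules))
        if (!nrow(boxes)) next
        idx <- which(rec@mask == 1L, arr.ind = TRUE)
        x <- idx[, 2L] - 1; y <- idx[, 1L] - 1
        covered <- rep(FALSE, nrow(idx))
        for (b in seq_len(nrow(boxes))) {
            covered <- covered |
                (x >= boxes$xmin[b] & x < boxes$xmax[b] &
                 y >= boxes$ymin[b] & y < boxes$ymax[b])
        }
        expect_true(all(covered))
    }
})

test_that("infeasible nodule geometry is rejected with a diagnostic", {
    spec <- fixtureSpec(nPatients = 1L, slicesPerPatient = 1L,
                        noduleCountDist = c(0, 1, 0, 0, 0, 0),
                        areaRangePx = c(5000, 5000), imageSize = 48L)
    expect_error(generateDataset(spec), "infeasible")
})

test_that("a perfect teacher reproduces the ground truth with confidence 1", {
    ss <- tinySet()
    st <- simulateTeacher(ss, qualityOfTeacher = 1.0, seed = 2L)
    for (i in seq_along(st)) {
        rec <- ss[[i]]; s <- st[[i]]
        expect_equal(nrow(s@boxes), nrow(rec@nodules))
        if (nrow(s@boxes)) {
            expect_equal(as.matrix(s@boxes),
                         unname(as.matrix(rec@nodules[, c("xmin", "ymin",
                                                          "xmax", "ymax")])),
                         ignore_attr = TRUE)
            expect_true(all(s@confidences == 1))
        }
        # raw model-driven score collapses to the density term
        r <- scoreModel(s)
        expect_equal(r$cDetRaw, min(0.5 * s@nGt, 2.0), tolerance = 1e-12)
    }
})

test_that("a useless teacher usually emits no boxes", {
    rec <- makeRecord("q0_s1", areas = 600)
    rec@image <- matrix(0, 64, 64)
    ss <- new("SliceSet", slices = list(rec))
    emptyCount <- sum(vapply(1:120, function(sd) {
        nrow(simulateTeacher(ss, qualityOfTeacher = 0, seed = sd)[[1]]@boxes) == 0L
    }, logical(1)))
    expect_gt(emptyCount / 120, 0.5)
})

test_that("teacher always emits five descending pre-NMS scores", {
    ss <- tinySet()
    for (q in c(0, 0.4, 0.8, 1)) {
        st <- simulateTeacher(ss, q, seed = 7L)
        expect_true(all(vapply(st, function(s)
            length(s@preNmsScores) == 5L &&
            !is.unsorted(rev(s@preNmsScores)), logical(1))))
    }
    expect_identical(simulateTeacher(new("SliceSet", slices = list()),
                                     0.5, 1L), list())
})
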