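box <- function(x0, y0, x1, y1, sid = "s1", conf = NULL) {
    b <- data.frame(sliceId = sid, xmin = x0, ymin = y0, xmax = x1, ymax = y1)
    if (!is.null(conf)) b$confidence <- conf
    b
}

test_that("IoU follows the half-open area arithmetic", {
    a <- box(0, 0, 10, 10)[, -1]
    expect_equal(boxIou(a, a)[1, 1], 1.0)
    expect_equal(boxIou(a, box(5, 0, 15, 10)[, -1])[1, 1], 1 / 3)
    expect_equal(boxIou(a, box(20, 20, 30, 30)[, -1])[1, 1], 0)
    expect_equal(boxIou(a, box(10, 0, 20, 10)[, -1])[1, 1], 0)  # touching
})

test_that("matching is one-to-one, greedy by confidence", {
    gt <- box(0, 0, 10, 10)
    m <- matchDetections(box(0, 0, 10, 14, conf = 0.9), gt, 0.5)  # IoU 10/14
    expect_identical(c(m$tp, m$fp, m$fn), c(1L, 0L, 0L))

    m <- matchDetections(box(0, 0, 10, 25, conf = 0.9), gt, 0.5)  # IoU 0.4
    expect_identical(c(m$tp, m$fp, m$fn), c(0L, 1L, 1L))

    # two good predictions on one GT: only the more confident is TP
    two <- rbind(box(0, 0, 10, 11, conf = 0.6), box(0, 0, 10, 12, conf = 0.8))
    m <- matchDetections(two, gt, 0.5)
    expect_identical(c(m$tp, m$fp, m$fn), c(1L, 1L, 0L))
    expect_identical(m$labels, c("FP", "TP"))  # row order of the input
})

test_that("precision and recall follow the count definitions", {
    expect_equal(precisionRecall(3, 1, 2),
                 c(precision = 0.75, recall = 0.6))
    expect_equal(precisionRecall(0, 0, 5),
                 c(precision = 0, recall = 0))
    expect_equal(precisionRecall(4, 0, 0),
                 c(precision = 1, recall = 1))
})

test_that("TP + FN equals the ground-truth count at every threshold", {
    for (seed in 1:20) {
        inst <- randomDetectionInstance(seed)
        for (tau in c(0.3, 0.5, 0.75)) {
            m <- matchDetections(inst$pred, inst$gt, tau)
            expect_identical(m$tp + m$fn, nrow(inst$gt))
        }
    }
})

test_that("the hand-computed AP case gives 5/6", {
    gt <- rbind(box(0, 0, 10, 10), box(50, 50, 60, 60))
    pred <- rbind(box(0, 0, 10, 10, conf = 0.9),     # TP
                  box(80, 80, 90, 90, conf = 0.8),   # FP
                  box(50, 50, 60, 60, conf = 0.7))   # TP
    expect_equal(averagePrecision(pred, gt, 0.5), 5 / 6, tolerance = 1e-12)
})

test_that("AP is 1 for perfect predictions and drops with a leading FP", {
    gt <- rbind(box(0, 0, 10, 10), box(50, 50, 60, 60, sid = "s2"))
    perfect <- rbind(box(0, 0, 10, 10, conf = 0.9),
                     box(50, 50, 60, 60, sid = "s2", conf = 0.8))
    expect_equal(averagePrecision(perfect, gt, 0.5), 1.0)
    withFp <- rbind(box(80, 80, 90, 90, conf = 0.95), perfect)
    expect_lt(averagePrecision(withFp, gt, 0.5), 1.0)
})

test_that("AP depends only on the confidence ranking", {
    inst <- randomDetectionInstance(101)
    a <- averagePrecision(inst$pred, inst$gt, 0.5)
    scaled <- inst$pred
    scaled$confidence <- scaled$confidence * 0.37
    expect_equal(averagePrecision(scaled, inst$gt, 0.5), a, tolerance = 1e-12)
})

test_that("degenerate evaluations behave by convention", {
    gt <- box(0, 0, 10, 10)
    noPred <- box(0, 0, 1, 1, conf = 1)[0, ]
    res <- evaluateDetections(noPred, gt)
    expect_equal(res@recall, 0)
    expect_equal(res@map50, 0)
    expect_warning(averagePrecision(box(0, 0, 5, 5, conf = 1), gt[0, ], 0.5),
                   "undefined")
})

test_that("full evaluation matches the brute-force evaluator exactly", {
    for (seed in 1:110) {
        inst <- randomDetectionInstance(seed, nSlices = 2L)
        got <- averagePrecision(inst$pred, inst$gt, 0.5)
        want <- bruteAP(inst$pred, inst$gt, 0.5)
        expect_equal(got, want, tolerance = 1e-10)
    }
    # complete metric set on a larger pooled instance
    inst <- randomDetectionInstance(7, nSlices = 20L)
    res <- evaluateDetections(inst$pred, inst$gt)
    ref <- bruteEvaluate(inst$pred, inst$gt)
    expect_equal(res@precision, ref$precision, tolerance = 1e-10)
    expect_equal(res@recall, ref$recall, tolerance = 1e-10)
    expect_equal(unname(res@apPerTau), ref$ap, tolerance = 1e-10)
    expect_equal(res@map50, ref$map50, tolerance = 1e-10)
    expect_equal(res@map50_95, ref$map50_95, tolerance = 1e-10)
    # structural identities
    expect_equal(res@map50, res@apPerTau[["0.50"]])
    expect_equal(res@map50_95, mean(res@apPerTau))
    expect_lte(res@map50_95, res@map50 + 1e-12)
})

test_that("perfect predictions give unit metrics end to end", {
    ss <- tinySet()
    st <- simulateTeacher(ss, 1.0, seed = 3L)
    res <- evaluateDetections(summariesToPredictions(st),
                              groundTruthBoxes(ss))
    expect_equal(res@precision, 1)
    expect_equal(res@recall, 1)
    expect_equal(res@map50, 1)
    expect_equal(res@map50_95, 1)
})
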