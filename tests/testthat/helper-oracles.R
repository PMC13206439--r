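# Independent oracles used to cross-check the package implementations.
# These are deliberately written as naive loop-based transcriptions and
# share no code with the package internals.

# --- model-driven difficulty: literal transcription --------------------

eq3Literal <- function(nPred, nGt, pBar, l1 = 3.0, l2 = 3.0, l3 = 1.0,
                       lo = 0.5, hi = 8.0) {
    raw <- l1 * (1 - pBar) +
        l2 * abs(nPred - nGt) / max(nGt, 1) +
        l3 * min(0.5 * nPred, 2.0)
    min(max(raw, lo), hi)
}

# --- handcrafted score: independent tabulation -------------------------

oracleCountFactor <- function(n) {
    if (n == 0) 0.5 else if (n == 1) 1.0 else if (n <= 3) 2.5 else 4.0
}
oracleSizeFactor <- function(areas) {
    if (length(areas) == 0) return(0.5)
    m <- min(areas)
    if (m > 1000) 1.0 else if (m >= 400) 2.0 else 3.0
}
oracleShapeFactor <- function(ars, thr = 2.0) {
    k <- sum(ars > thr)
    if (k == 0) 0.5 else if (k == 1) 1.0 else 2.0
}
oracleQualityFactor <- function(tier) {
    switch(tier, high = 0.5, medium = 1.0, low = 2.0)
}

# --- detection metrics: brute-force evaluator --------------------------

bruteIou <- function(a, b) {
    ix <- min(a[3], b[3]) - max(a[1], b[1])
    iy <- min(a[4], b[4]) - max(a[2], b[2])
    if (ix <= 0 || iy <= 0) return(0)
    inter <- ix * iy
    areaA <- (a[3] - a[1]) * (a[4] - a[2])
    areaB <- (b[3] - b[1]) * (b[4] - b[2])
    inter / (areaA + areaB - inter)
}

# Greedy confidence-ordered one-to-one matching, O(n^2) loops.
bruteMatch <- function(pred, gt, tau) {
    ord <- order(-pred$confidence)
    matched <- rep(FALSE, nrow(gt))
    isTp <- rep(FALSE, nrow(pred))
    for (i in ord) {
        best <- -1; bj <- 0L
        for (j in seq_len(nrow(gt))) {
            if (matched[j] || gt$sliceId[j] != pred$sliceId[i]) next
            v <- bruteIou(as.numeric(pred[i, c("xmin", "ymin", "xmax", "ymax")]),
                          as.numeric(gt[j, c("xmin", "ymin", "xmax", "ymax")]))
            if (v >= tau && v > best) { best <- v; bj <- j }
        }
        if (bj > 0L) { matched[bj] <- TRUE; isTp[i] <- TRUE }
    }
    list(isTp = isTp, order = ord, fn = sum(!matched))
}

# Exact area under the monotone precision envelope, loop form.
bruteAP <- function(pred, gt, tau) {
    if (nrow(gt) == 0) return(0)
    if (nrow(pred) == 0) return(0)
    m <- bruteMatch(pred, gt, tau)
    flags <- m$isTp[m$order]
    n <- length(flags)
    prec <- numeric(n); rec <- numeric(n)
    tp <- 0
    for (i in seq_len(n)) {
        if (flags[i]) tp <- tp + 1
        prec[i] <- tp / i
        rec[i] <- tp / nrow(gt)
    }
    ap <- 0; prev <- 0
    for (i in seq_len(n)) {
        ap <- ap + (rec[i] - prev) * max(prec[i:n])
        prev <- rec[i]
    }
    ap
}

bruteEvaluate <- function(pred, gt, confThreshold = 0.1,
                          taus = seq(0.5, 0.95, by = 0.05)) {
    keep <- pred[pred$confidence >= confThreshold, , drop = FALSE]
    m <- bruteMatch(keep, gt, 0.5)
    tp <- sum(m$isTp); fp <- nrow(keep) - tp; fn <- m$fn
    ap <- vapply(taus, function(tau) bruteAP(pred, gt, tau), numeric(1))
    list(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
         recall = if (tp + fn > 0) tp / (tp + fn) else 0,
         ap = ap, map50 = ap[1], map50_95 = mean(ap))
}

# Random small detection instance: a few slices, jittered true positives
# plus spurious boxes, distinct confidences almost surely.
randomDetectionInstance <- function(seed, nSlices = 3L, size = 100) {
    set.seed(seed)
    gt <- NULL; pred <- NULL
    for (s in seq_len(nSlices)) {
        sid <- sprintf("s%02d", s)
        nG <- sample(0:4, 1L)
        if (nG > 0) {
            w <- runif(nG, 8, 30); h <- runif(nG, 8, 30)
            x0 <- runif(nG, 0, size - w); y0 <- runif(nG, 0, size - h)
            gt <- rbind(gt, data.frame(sliceId = sid, xmin = x0, ymin = y0,
                                       xmax = x0 + w, ymax = y0 + h))
            hit <- runif(nG) < 0.7
            if (any(hit)) {
                j <- which(hit)
                d <- matrix(rnorm(4 * length(j), sd = 3), ncol = 4)
                pred <- rbind(pred, data.frame(
                    sliceId = sid,
                    xmin = x0[j] + d[, 1], ymin = y0[j] + d[, 2],
                    xmax = x0[j] + w[j] + d[, 3], ymax = y0[j] + h[j] + d[, 4],
                    confidence = runif(length(j))))
            }
        }
        nF <- sample(0:3, 1L)
        if (nF > 0) {
            w <- runif(nF, 8, 30); h <- runif(nF, 8, 30)
            x0 <- runif(nF, 0, size - w); y0 <- runif(nF, 0, size - h)
            pred <- rbind(pred, data.frame(sliceId = sid, xmin = x0, ymin = y0,
                                           xmax = x0 + w, ymax = y0 + h,
                                           confidence = runif(nF)))
        }
    }
    emptyP <- data.frame(sliceId = character(0), xmin = numeric(0),
                         ymin = numeric(0), xmax = numeric(0),
                         ymax = numeric(0), confidence = numeric(0))
    emptyG <- emptyP[, -6]
    if (!is.null(pred)) pred$xmax <- pmax(pred$xmax, pred$xmin + 1)
    if (!is.null(pred)) pred$ymax <- pmax(pred$ymax, pred$ymin + 1)
    list(pred = if (is.null(pred)) emptyP else pred,
         gt = if (is.null(gt)) emptyG else gt)
}
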