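#' Intersection over union of boxes
#'
#' IoU under the half-open pixel convention, so areas are exact products of
#' side lengths. Disjoint boxes score 0.
#'
#' @param a,b data.frames of boxes (\code{xmin, ymin, xmax, ymax}); all
#'   pairs are compared.
#' @return Numeric matrix of dimension \code{nrow(a) x nrow(b)}.
#' @examples
#' boxIou(data.frame(xmin = 0, ymin = 0, xmax = 10, ymax = 10),
#'        data.frame(xmin = 5, ymin = 0, xmax = 15, ymax = 10))  # 1/3
#' @export
boxIou <- function(a, b) {
    a <- asBoxFrame(a); b <- asBoxFrame(b)
    n <- nrow(a); m <- nrow(b)
    if (n == 0L || m == 0L) return(matrix(numeric(0), n, m))
    ix <- pmax(0, outer(a$xmax, b$xmax, pmin) - outer(a$xmin, b$xmin, pmax))
    iy <- pmax(0, outer(a$ymax, b$ymax, pmin) - outer(a$ymin, b$ymin, pmax))
    inter <- ix * iy
    areaA <- (a$xmax - a$xmin) * (a$ymax - a$ymin)
    areaB <- (b$xmax - b$xmin) * (b$ymax - b$ymin)
    un <- outer(areaA, areaB, `+`) - inter
    ifelse(un > 0, inter / un, 0)
}

# Greedy one-to-one matching of one slice's predictions (already in
# descending-confidence order) against its ground truths at IoU >= tau.
# Returns logical TP flags per prediction.
greedyMatchSlice <- function(predBoxes, gtBoxes, tau) {
    nP <- nrow(predBoxes); nG <- nrow(gtBoxes)
    tp <- logical(nP)
    if (nP == 0L) return(tp)
    if (nG == 0L) return(tp)
    iou <- boxIou(predBoxes, gtBoxes)
    taken <- logical(nG)
    for (i in seq_len(nP)) {
        cand <- which(!taken & iou[i, ] >= tau)
        if (length(cand)) {
            j <- cand[which.max(iou[i, cand])]
            taken[j] <- TRUE
            tp[i] <- TRUE
        }
    }
    tp
}

#' Match predictions against ground truth at one IoU threshold
#'
#' Greedy one-to-one matching in descending confidence order: each
#' prediction is matched to the unmatched ground-truth box of its slice
#' with the highest IoU, provided IoU >= \code{tau}; matched predictions
#' are true positives, the rest false positives, and unmatched ground
#' truths are false negatives. \code{TP + FN} always equals the number of
#' ground-truth boxes.
#'
#' @param predictions data.frame with \code{sliceId, xmin, ymin, xmax,
#'   ymax, confidence}.
#' @param gts data.frame with \code{sliceId, xmin, ymin, xmax, ymax}.
#' @param tau IoU threshold in (0, 1].
#' @return List with \code{labels} (character "TP"/"FP" per prediction, in
#'   the input row order), \code{tp}, \code{fp}, \code{fn} counts and
#'   \code{tau}.
#' @export
matchDetections <- function(predictions, gts, tau = 0.5) {
    stopifnot(tau > 0, tau <= 1)
    predictions <- as.data.frame(predictions)
    gts <- as.data.frame(gts)
    labels <- character(nrow(predictions))
    tpTotal <- 0L
    for (sid in unique(c(predictions$sliceId, gts$sliceId))) {
        pi <- which(predictions$sliceId == sid)
        gi <- which(gts$sliceId == sid)
        ord <- pi[order(-predictions$confidence[pi])]
        tp <- greedyMatchSlice(predictions[ord, , drop = FALSE],
                               gts[gi, , drop = FALSE], tau)
        labels[ord] <- ifelse(tp, "TP", "FP")
        tpTotal <- tpTotal + sum(tp)
    }
    list(labels = labels, tp = as.integer(tpTotal),
         fp = as.integer(nrow(predictions) - tpTotal),
         fn = as.integer(nrow(gts) - tpTotal), tau = tau)
}

#' Precision and recall from match counts
#'
#' \code{precision = TP / (TP + FP)} and \code{recall = TP / (TP + FN)};
#' a zero denominator yields 0 by convention.
#'
#' @param tp,fp,fn non-negative counts.
#' @return Named numeric vector \code{c(precision, recall)}.
#' @export
precisionRecall <- function(tp, fp, fn) {
    stopifnot(tp >= 0, fp >= 0, fn >= 0)
    c(precision = if (tp + fp > 0) tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) tp / (tp + fn) else 0)
}

# PR sweep shared by averagePrecision and evaluateDetections: global
# descending-confidence ranking, per-slice greedy matching, cumulative
# precision/recall.
prSweep <- function(predictions, gts, tau) {
    nGt <- nrow(gts)
    ord <- order(-predictions$confidence)
    pred <- predictions[ord, , drop = FALSE]
    tp <- logical(nrow(pred))
    for (sid in unique(pred$sliceId)) {
        pi <- which(pred$sliceId == sid)
        gi <- which(gts$sliceId == sid)
        tp[pi] <- greedyMatchSlice(pred[pi, , drop = FALSE],
                                   gts[gi, , drop = FALSE], tau)
    }
    cumTp <- cumsum(tp)
    cumFp <- cumsum(!tp)
    data.frame(recall = if (nGt > 0) cumTp / nGt else rep(0, length(cumTp)),
               precision = cumTp / pmax(1L, cumTp + cumFp))
}

# Exact all-point area under the monotone precision envelope.
envelopeArea <- function(pr) {
    if (!nrow(pr)) return(0)
    penv <- rev(cummax(rev(pr$precision)))
    dr <- diff(c(0, pr$recall))
    sum(dr * penv)
}

#' Average precision at one IoU threshold
#'
#' Area under the precision-recall curve: predictions are ranked by
#' descending confidence over the whole dataset (micro, all slices
#' pooled), matched greedily one-to-one per slice, and the area is
#' integrated exactly over all recall change-points under the monotone
#' precision envelope (all-point interpolation, not 11- or 101-point
#' sampling). AP depends only on the ranking, not on the confidence
#' scale. With no ground-truth boxes in the evaluation set, AP is
#' undefined and reported as 0 with a warning.
#'
#' @inheritParams matchDetections
#' @return Scalar AP in [0, 1].
#' @export
averagePrecision <- function(predictions, gts, tau = 0.5) {
    stopifnot(tau > 0, tau <= 1)
    predictions <- as.data.frame(predictions)
    gts <- as.data.frame(gts)
    if (!nrow(gts)) {
        warning("no ground-truth boxes: AP undefined, reporting 0")
        return(0)
    }
    if (!nrow(predictions)) return(0)
    envelopeArea(prSweep(predictions, gts, tau))
}

#' Evaluate detections: precision, recall, mAP50, mAP50-95
#'
#' Full detection evaluation. Precision and recall are reported at the
#' operating point confidence >= \code{confThreshold} (default 0.1) and
#' IoU 0.5; AP(\eqn{\tau}) is computed over the full ranking (no
#' confidence cut) for \eqn{\tau \in \{0.50, 0.55, \ldots, 0.95\}};
#' mAP50 = AP(0.50) and mAP50-95 is the mean of the ten AP values. The
#' conventions (greedy one-to-one confidence matching, exact all-point
#' envelope integration, micro pooling) are recorded in the result's
#' metadata.
#'
#' @inheritParams matchDetections
#' @param confThreshold operating-point confidence threshold in (0, 1].
#' @param iouThresholds IoU thresholds for the AP sweep.
#' @return An \linkS4class{EvalResult}.
#' @export
evaluateDetections <- function(predictions, gts, confThreshold = 0.1,
                               iouThresholds = seq(0.5, 0.95, by = 0.05)) {
    stopifnot(confThreshold > 0, confThreshold <= 1)
    predictions <- as.data.frame(predictions)
    gts <- as.data.frame(gts)
    keep <- predictions$confidence >= confThreshold
    op <- matchDetections(predictions[keep, , drop = FALSE], gts, tau = 0.5)
    pr <- precisionRecall(op$tp, op$fp, op$fn)
    noGt <- nrow(gts) == 0L
    if (noGt) warning("no ground-truth boxes: AP undefined, reporting 0")
    curves <- lapply(iouThresholds, function(tau) {
        if (noGt || !nrow(predictions))
            data.frame(recall = numeric(0), precision = numeric(0))
        else prSweep(predictions, gts, tau)
    })
    ap <- vapply(curves, envelopeArea, numeric(1))
    names(ap) <- sprintf("%.2f", iouThresholds)
    names(curves) <- names(ap)
    new("EvalResult",
        precision = unname(pr["precision"]), recall = unname(pr["recall"]),
        apPerTau = ap,
        map50 = unname(ap[["0.50"]]),
        map50_95 = mean(ap),
        counts = c(tp = op$tp, fp = op$fp, fn = op$fn),
        prCurves = curves,
        metadata = list(matcher = "greedy one-to-one, descending confidence",
                        integration = "exact all-point monotone envelope",
                        pooling = "micro (all slices pooled)",
                        confThreshold = confThreshold,
                        apUsesConfThreshold = FALSE))
}

#' Ground-truth boxes of a slice set as an evaluation frame
#'
#' @param records a \linkS4class{SliceSet}.
#' @return data.frame with \code{sliceId, xmin, ymin, xmax, ymax}, one row
#'   per nodule.
#' @export
groundTruthBoxes <- function(records) {
    stopifnot(is(records, "SliceSet"))
    rows <- lapply(records@slices, function(rec) {
        if (!nrow(rec@nodules)) return(NULL)
        data.frame(sliceId = rec@sliceId,
                   rec@nodules[, c("xmin", "ymin", "xmax", "ymax")])
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(sliceId = character(0), xmin = numeric(0),
                          ymin = numeric(0), xmax = numeric(0),
                          ymax = numeric(0))
    rownames(out) <- NULL
    out
}

#' Pool detection summaries into an evaluation frame
#'
#' @param summaries list of \linkS4class{DetectionSummary}.
#' @return data.frame with \code{sliceId, xmin, ymin, xmax, ymax,
#'   confidence}, one row per post-NMS box.
#' @export
summariesToPredictions <- function(summaries) {
    rows <- lapply(summaries, function(s) {
        if (!nrow(s@boxes)) return(NULL)
        data.frame(sliceId = s@sliceId, s@boxes,
                   confidence = s@confidences)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(sliceId = character(0), xmin = numeric(0),
                          ymin = numeric(0), xmax = numeric(0),
                          ymax = numeric(0), confidence = numeric(0))
    rownames(out) <- NULL
    out
}
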