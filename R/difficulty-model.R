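#' Construct model-driven difficulty parameters
#'
#' @param lambda1,lambda2,lambda3 non-negative weights of the confidence,
#'   count-discrepancy and prediction-density terms (defaults 3.0, 3.0,
#'   1.0: confidence and count mismatch reflect detector failure most
#'   directly, density is an auxiliary penalty).
#' @param clipLow,clipHigh output clipping bounds (defaults 0.5 and 8.0,
#'   preventing extreme outliers from dominating the curriculum ranking).
#' @return A \linkS4class{ModelDifficultyParams}.
#' @export
modelDifficultyParams <- function(lambda1 = 3.0, lambda2 = 3.0,
                                  lambda3 = 1.0, clipLow = 0.5,
                                  clipHigh = 8.0) {
    new("ModelDifficultyParams", lambda1 = lambda1, lambda2 = lambda2,
        lambda3 = lambda3, clipLow = clipLow, clipHigh = clipHigh)
}

#' Mean detector confidence for a slice
#'
#' Returns the mean confidence of the post-NMS boxes when at least one box
#' survives NMS, and one minus the mean of the top-5 pre-NMS candidate
#' scores when none does, so that a higher value consistently indicates
#' higher detector confidence. Fewer than five pre-NMS candidates are
#' padded with zeros before averaging (biasing the surrogate upward only
#' when the detector truly found almost nothing). With no boxes and no
#' pre-NMS scores at all, the worst case 0 is returned with a warning.
#'
#' @param x a \linkS4class{DetectionSummary}.
#' @param ... unused.
#' @return Scalar in [0, 1].
#' @rdname meanConfidence
#' @export
setMethod("meanConfidence", "DetectionSummary", function(x, ...) {
    if (nrow(x@boxes) >= 1L) return(mean(x@confidences))
    if (!length(x@preNmsScores)) {
        warning(sprintf(paste0("slice %s: no boxes and no pre-NMS scores; ",
                               "falling back to mean confidence 0"),
                        x@sliceId))
        return(0)
    }
    top5 <- c(x@preNmsScores, rep(0, 5L))[1:5]
    1 - mean(top5)
})

#' Model-driven difficulty from raw components
#'
#' Evaluates
#' \deqn{c_{det} = clip(\lambda_1 (1 - \bar p)
#'   + \lambda_2 |N_{pred} - N_{gt}| / \max(N_{gt}, 1)
#'   + \lambda_3 \min(0.5 N_{pred}, 2), c_{low}, c_{high})}
#' vectorized over its arguments. The three terms penalize low-confidence
#' predictions, counting discrepancies, and overly dense predictions (the
#' density term saturates at \eqn{2 \lambda_3} from four predictions on).
#'
#' @param pBar mean detector confidence in [0, 1]
#'   (see \code{\link{meanConfidence}}).
#' @param nPred number of post-NMS predicted boxes.
#' @param nGt ground-truth nodule count.
#' @param params a \linkS4class{ModelDifficultyParams}.
#' @return Clipped difficulty score(s) in \code{[clipLow, clipHigh]}.
#' @examples
#' modelDifficulty(0.9, 2, 2)   # 1.3
#' modelDifficulty(1.0, 0, 0)   # clipped up to 0.5
#' modelDifficulty(0.2, 10, 1)  # clipped down to 8.0
#' @export
modelDifficulty <- function(pBar, nPred, nGt,
                            params = modelDifficultyParams()) {
    stopifnot(is(params, "ModelDifficultyParams"))
    validObject(params)
    raw <- params@lambda1 * (1 - pBar) +
        params@lambda2 * abs(nPred - nGt) / pmax(nGt, 1) +
        params@lambda3 * pmin(0.5 * nPred, 2.0)
    pmin(params@clipHigh, pmax(params@clipLow, raw))
}

#' Model-driven difficulty score for a prediction summary
#'
#' Computes the mean-confidence surrogate of the summary and evaluates the
#' model-driven difficulty (\code{\link{modelDifficulty}}).
#'
#' @param x a \linkS4class{DetectionSummary}.
#' @param params a \linkS4class{ModelDifficultyParams}.
#' @param ... unused.
#' @return One-row data.frame \code{sliceId, pBar, cDetRaw, cDet}.
#' @rdname scoreModel
#' @export
setMethod("scoreModel", "DetectionSummary", function(x, params =
                                                     modelDifficultyParams(),
                                                     ...) {
    pBar <- meanConfidence(x)
    nPred <- nrow(x@boxes)
    raw <- params@lambda1 * (1 - pBar) +
        params@lambda2 * abs(nPred - x@nGt) / max(x@nGt, 1) +
        params@lambda3 * min(0.5 * nPred, 2.0)
    data.frame(sliceId = x@sliceId, pBar = pBar, cDetRaw = raw,
               cDet = min(params@clipHigh, max(params@clipLow, raw)))
})

#' Score the held-out subset with leakage guarding
#'
#' Applies \code{\link{scoreModel}} to a collection of teacher prediction
#' summaries while enforcing that difficulty scores are only assigned on
#' samples the teacher never saw: every scored slice must belong to a
#' patient of the scoring held-out set of \code{\link{teacherSplit}}.
#' In-sample scoring is rejected with the offending patient ids.
#'
#' @param summaries list of \linkS4class{DetectionSummary}.
#' @param split result of \code{\link{teacherSplit}} (or any list with a
#'   \code{scoringHeldout} patient-id vector).
#' @param patientOfSlice named character vector mapping slice id to patient
#'   id (e.g. \code{setNames(patientId(set), sliceId(set))}).
#' @param params a \linkS4class{ModelDifficultyParams}.
#' @return data.frame with one row per summary:
#'   \code{sliceId, pBar, cDetRaw, cDet}.
#' @export
scoreHeldout <- function(summaries, split, patientOfSlice,
                         params = modelDifficultyParams()) {
    if (!length(summaries))
        return(data.frame(sliceId = character(0), pBar = numeric(0),
                          cDetRaw = numeric(0), cDet = numeric(0)))
    ids <- vapply(summaries, function(s) s@sliceId, character(1))
    pats <- patientOfSlice[ids]
    if (anyNA(pats))
        stop(sprintf("unknown patient for slice(s): %s",
                     paste(ids[is.na(pats)], collapse = ", ")))
    bad <- setdiff(unique(pats), split$scoringHeldout)
    if (length(bad))
        stop(sprintf(paste0("in-sample scoring forbidden: patient(s) %s are ",
                            "not in the scoring held-out set"),
                     paste(sort(bad), collapse = ", ")))
    out <- do.call(rbind, lapply(summaries, scoreModel, params = params))
    rownames(out) <- NULL
    out
}
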