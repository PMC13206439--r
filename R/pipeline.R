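#' End-to-end curriculum pipeline on one slice set
#'
#' Runs the full workflow on a (typically synthetic) dataset: quality
#' metrics, sub-3 mm nodule filtering, nodule-oriented slice sampling,
#' CLAHE, handcrafted and model-driven difficulty scoring (the teacher
#' summaries come from \code{\link{simulateTeacher}} unless supplied),
#' hybrid fusion and tiering, curriculum construction, and evaluation of
#' the teacher predictions against the ground truth. Every random step is
#' driven by seeds derived from the single \code{seed} argument, so the
#' whole run is reproducible from one knob.
#'
#' @param records a \linkS4class{SliceSet}; by default a fresh synthetic
#'   dataset is generated from \code{spec}.
#' @param spec a \linkS4class{FixtureSpec} used when \code{records} is
#'   missing.
#' @param a mixing coefficient of the hybrid fusion.
#' @param teacherQuality quality knob of the simulated teacher.
#' @param summaries optional list of \linkS4class{DetectionSummary}
#'   replacing the simulated teacher.
#' @param sampleRatio non-nodule : nodule slice retention ratio.
#' @param seed integer master seed.
#' @return Named list: \code{records} (preprocessed slice set),
#'   \code{manual} and \code{model} score tables, \code{scores} (merged,
#'   with \code{cHybrid} and \code{tier}), \code{manifest}
#'   (\linkS4class{CurriculumManifest}), \code{evaluation}
#'   (\linkS4class{EvalResult}) and \code{summaries}.
#' @export
curriculumPipeline <- function(records = NULL, spec = fixtureSpec(seed = seed),
                               a = 0.2, teacherQuality = 0.7,
                               summaries = NULL, sampleRatio = 2.0,
                               seed = 1L) {
    if (is.null(records)) records <- generateDataset(spec)
    records <- computeQualitySet(records)     # metrics on the raw slices
    records <- filterSmallNodules(records)
    records <- sampleSlices(records, ratio = sampleRatio,
                            seed = deriveSeed(seed, 2L))
    records@slices <- lapply(records@slices, applyClahe)
    if (is.null(summaries))
        summaries <- simulateTeacher(records, teacherQuality,
                                     seed = deriveSeed(seed, 3L))
    manual <- scoreManual(records)
    model <- do.call(rbind, lapply(summaries, scoreModel))
    scores <- merge(manual, model, by = "sliceId", sort = FALSE)
    scores$cHybrid <- fuseDifficulty(scores$cManual, scores$cDet, a)
    scores$tier <- assignTier(scores$cHybrid)
    scores$isPositive <- noduleCounts(records)[
        match(scores$sliceId, sliceId(records))] > 0L
    scores$qualityTier <- qualityTier(records)[
        match(scores$sliceId, sliceId(records))]
    manifest <- suppressWarnings(buildCurriculum(
        scores,
        provenance = list(a = a, teacherQuality = teacherQuality,
                          sampleRatio = sampleRatio, seed = seed)))
    evaluation <- evaluateDetections(summariesToPredictions(summaries),
                                     groundTruthBoxes(records))
    list(records = records, manual = manual, model = model, scores = scores,
         manifest = manifest, evaluation = evaluation, summaries = summaries)
}
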