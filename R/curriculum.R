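#' Fuse handcrafted and model-driven difficulty
#'
#' Convex combination
#' \deqn{c_{hybrid} = a \, c_{manual} + (1 - a) \, c_{det}}
#' where the mixing coefficient \eqn{a \in [0, 1]} controls the relative
#' contribution of the two sources: \eqn{a = 1} is a purely handcrafted
#' curriculum, \eqn{a = 0} a purely detector-driven one. The default 0.2 is
#' the ablation optimum and is exposed as a parameter.
#'
#' @param cManual,cDet numeric vectors of per-slice scores (recycled).
#' @param a mixing coefficient in [0, 1].
#' @return Numeric vector of fused scores, always between the two inputs.
#' @examples
#' fuseDifficulty(3.0, 1.3, a = 0.2)  # 1.64
#' @export
fuseDifficulty <- function(cManual, cDet, a = 0.2) {
    if (length(a) != 1L || is.na(a) || a < 0 || a > 1)
        stop("mixing coefficient a must be a scalar in [0, 1]")
    a * cManual + (1 - a) * cDet
}

#' Assign difficulty tiers
#'
#' Thresholds the fused score into the three curriculum tiers:
#' simple (\eqn{c \le 3}), medium (\eqn{3 < c \le 6}) and complex
#' (\eqn{c > 6}).
#'
#' @param cHybrid numeric vector of fused difficulty scores.
#' @param simpleMax,mediumMax tier boundaries (defaults 3 and 6, both
#'   inclusive on the lower tier).
#' @return Character vector in \code{c("simple", "medium", "complex")}.
#' @export
assignTier <- function(cHybrid, simpleMax = 3, mediumMax = 6) {
    ifelse(cHybrid <= simpleMax, "simple",
    ifelse(cHybrid <= mediumMax, "medium", "complex"))
}

stageConfig <- function(stageIndex, inputResolution, epochs, learningRate,
                        lossWeights, augmentation, includedTiers,
                        includedNegativeQuality) {
    new("StageConfig",
        stageIndex = as.integer(stageIndex),
        inputResolution = as.integer(inputResolution),
        epochs = as.integer(epochs),
        learningRate = learningRate,
        lossWeights = lossWeights,
        augmentation = augmentation,
        includedTiers = includedTiers,
        includedNegativeQuality = includedNegativeQuality)
}

#' Default three-stage curriculum configurations
#'
#' The progressive schedule: stage 1 trains on simple positives plus
#' high-quality negatives at 512 px for 50 epochs (lr 0.003, loss weights
#' box 2.0 / cls 4.0 / dfl 0.1, augmentation 3 deg / 5\% / 10\%); stage 2
#' adds medium positives and medium-quality negatives at 640 px for 100
#' epochs (lr 0.002, box 5.0 / cls 2.0 / dfl 0.5, 8 deg / 10\% / 20\%);
#' stage 3 uses the full training set at 768 px for 100 epochs (lr 0.001,
#' box 7.0 / cls 1.5 / dfl 1.0, 12 deg / 15\% / 30\%).
#'
#' @return List of three \linkS4class{StageConfig} objects.
#' @export
defaultStageConfigs <- function() {
    list(
        stageConfig(1L, 512L, 50L, 0.003,
            c(box = 2.0, cls = 4.0, dfl = 0.1),
            c(rotationDeg = 3, translationFrac = 0.05, scaleFrac = 0.10),
            "simple", "high"),
        stageConfig(2L, 640L, 100L, 0.002,
            c(box = 5.0, cls = 2.0, dfl = 0.5),
            c(rotationDeg = 8, translationFrac = 0.10, scaleFrac = 0.20),
            c("simple", "medium"), c("high", "medium")),
        stageConfig(3L, 768L, 100L, 0.001,
            c(box = 7.0, cls = 1.5, dfl = 1.0),
            c(rotationDeg = 12, translationFrac = 0.15, scaleFrac = 0.30),
            c("simple", "medium", "complex"), c("high", "medium", "low"))
    )
}

#' Build the three-stage progressive curriculum
#'
#' Assigns every training slice to the curriculum stages. Positive
#' (nodule-bearing) slices enter by difficulty tier (stage 1: simple;
#' stage 2: simple and medium; stage 3: all); negative slices enter by
#' image-quality tier (stage 1: high; stage 2: high and medium; stage 3:
#' all), so stage sample sets are cumulative and stage 3 covers the full
#' training set. Emits the per-stage slice-id lists together with the stage
#' configurations and full provenance.
#'
#' @param scores data.frame with one row per training slice and columns
#'   \code{sliceId}, \code{tier} (difficulty tier of positives),
#'   \code{isPositive} (logical) and \code{qualityTier} (of negatives).
#' @param stageTemplates list of three \linkS4class{StageConfig}
#'   (default \code{\link{defaultStageConfigs}()}).
#' @param provenance named list stored verbatim in the manifest (mixing
#'   coefficient, weights, seeds, ...).
#' @return A \linkS4class{CurriculumManifest}.
#' @export
buildCurriculum <- function(scores, stageTemplates = defaultStageConfigs(),
                            provenance = list()) {
    need <- c("sliceId", "tier", "isPositive", "qualityTier")
    stopifnot(all(need %in% names(scores)), length(stageTemplates) == 3L)
    pos <- scores[scores$isPositive, , drop = FALSE]
    neg <- scores[!scores$isPositive, , drop = FALSE]
    if (!any(pos$tier == "simple"))
        warning("no simple-tier positive slices: stage 1 would train on negatives only")
    stages <- lapply(stageTemplates, function(cfg) {
        c(pos$sliceId[pos$tier %in% cfg@includedTiers],
          neg$sliceId[neg$qualityTier %in% cfg@includedNegativeQuality])
    })
    new("CurriculumManifest", stages = stages, configs = stageTemplates,
        provenance = provenance)
}

#' No-curriculum baseline training configuration
#'
#' The conventional single-stage baseline: all training samples uniformly
#' shuffled and optimized jointly at a fixed input resolution of 640,
#' batch size 32, at most 500 epochs with early stopping (patience 30),
#' SGD with initial learning rate 1e-4, momentum 0.937 and weight decay
#' 5e-4, fixed loss weights box 5.0 / cls 2.0 / dfl 0.3, and evaluation at
#' confidence threshold 0.1 with IoU threshold 0.5.
#'
#' @return Named list with the baseline hyperparameters.
#' @export
baselineConfig <- function() {
    list(
        schedule = "uniform-shuffle",
        inputResolution = 640L,
        batchSize = 32L,
        maxEpochs = 500L,
        optimizer = "SGD",
        learningRate = 1e-4,
        momentum = 0.937,
        weightDecay = 5e-4,
        patience = 30L,
        lossWeights = c(box = 5.0, cls = 2.0, dfl = 0.3),
        confThreshold = 0.1,
        iouThreshold = 0.5
    )
}

#' Sweep the mixing coefficient
#'
#' Rebuilds the curriculum for each value of the mixing coefficient
#' \code{a} (duplicates removed) and reports tier occupancy per value; the
#' endpoints reproduce the purely detector-driven (\code{a = 0}) and purely
#' handcrafted (\code{a = 1}) curricula.
#'
#' @param scores data.frame with columns \code{sliceId, cManual, cDet,
#'   isPositive, qualityTier}.
#' @param aGrid numeric vector of mixing coefficients in [0, 1].
#' @param stageTemplates list of three \linkS4class{StageConfig}.
#' @return List with \code{table} (data.frame: a, nSimple, nMedium,
#'   nComplex) and \code{manifests} (one \linkS4class{CurriculumManifest}
#'   per a, named by a).
#' @export
sweepMixing <- function(scores, aGrid = seq(0, 1, by = 0.2),
                        stageTemplates = defaultStageConfigs()) {
    need <- c("sliceId", "cManual", "cDet", "isPositive", "qualityTier")
    stopifnot(all(need %in% names(scores)))
    aGrid <- sort(unique(aGrid))
    manifests <- list()
    rows <- list()
    for (a in aGrid) {
        ch <- fuseDifficulty(scores$cManual, scores$cDet, a)
        tier <- assignTier(ch)
        sc <- data.frame(sliceId = scores$sliceId, tier = tier,
                         isPositive = scores$isPositive,
                         qualityTier = scores$qualityTier)
        manifests[[as.character(a)]] <- suppressWarnings(
            buildCurriculum(sc, stageTemplates,
                            provenance = list(a = a)))
        rows[[as.character(a)]] <- data.frame(
            a = a,
            nSimple = sum(tier == "simple"),
            nMedium = sum(tier == "medium"),
            nComplex = sum(tier == "complex"))
    }
    list(table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         manifests = manifests)
}

#' Write / read a curriculum manifest as YAML
#'
#' Serializes the per-stage slice lists, the stage configurations and the
#' provenance to a YAML file; \code{readCurriculumManifest} reproduces
#' identical stage sample lists (round-trip identity).
#'
#' @param manifest a \linkS4class{CurriculumManifest}.
#' @param path YAML file path.
#' @return \code{writeCurriculumManifest}: the path, invisibly;
#'   \code{readCurriculumManifest}: a \linkS4class{CurriculumManifest}.
#' @export
writeCurriculumManifest <- function(manifest, path) {
    stopifnot(is(manifest, "CurriculumManifest"))
    cfgs <- lapply(manifest@configs, function(cfg) list(
        stageIndex = cfg@stageIndex,
        inputResolution = cfg@inputResolution,
        epochs = cfg@epochs,
        learningRate = cfg@learningRate,
        lossWeights = as.list(cfg@lossWeights),
        augmentation = as.list(cfg@augmentation),
        includedTiers = as.list(cfg@includedTiers),
        includedNegativeQuality = as.list(cfg@includedNegativeQuality)))
    yaml::write_yaml(list(
        stages = lapply(manifest@stages, as.list),
        configs = cfgs,
        provenance = manifest@provenance), path)
    invisible(path)
}

#' @rdname writeCurriculumManifest
#' @export
readCurriculumManifest <- function(path) {
    x <- yaml::read_yaml(path)
    cfgs <- lapply(x$configs, function(cfg) stageConfig(
        cfg$stageIndex, cfg$inputResolution, cfg$epochs, cfg$learningRate,
        unlist(cfg$lossWeights), unlist(cfg$augmentation),
        unlist(cfg$includedTiers), unlist(cfg$includedNegativeQuality)))
    new("CurriculumManifest",
        stages = lapply(x$stages, function(s) as.character(unlist(s))),
        configs = cfgs,
        provenance = x$provenance %||% list())
}
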