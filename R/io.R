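#' Write a slice set to a dataset directory
#'
#' Materializes a \linkS4class{SliceSet} in the interchange layout:
#' 8-bit PNG images under \code{images/}, binary PNG masks under
#' \code{masks/} (when present), YOLO-format label files under
#' \code{labels/}, and a \code{manifest.yaml} listing the patient-to-slice
#' mapping, pixel spacing and image size.
#'
#' @param records a \linkS4class{SliceSet}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @seealso \code{\link{readSliceSet}}
#' @export
writeSliceSet <- function(records, dir) {
    stopifnot(is(records, "SliceSet"))
    for (d in file.path(dir, c("images", "masks", "labels")))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
    entries <- lapply(records@slices, function(rec) {
        sid <- rec@sliceId
        EBImage::writeImage(rec@image / 255,
                            file.path(dir, "images", paste0(sid, ".png")))
        if (!is.null(rec@mask))
            EBImage::writeImage(rec@mask,
                                file.path(dir, "masks", paste0(sid, ".png")))
        writeLabels(rec@nodules[, c("xmin", "ymin", "xmax", "ymax"),
                                drop = FALSE],
                    c(ncol(rec@image), nrow(rec@image)),
                    file.path(dir, "labels", paste0(sid, ".txt")))
        list(sliceId = sid, patientId = rec@patientId,
             spacingMm = rec@spacingMm,
             height = nrow(rec@image), width = ncol(rec@image),
             hasMask = !is.null(rec@mask))
    })
    manifest <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(list(slices = entries), manifest)
    invisible(manifest)
}

#' Read a slice set from a dataset directory
#'
#' Inverse of \code{\link{writeSliceSet}}. Nodule annotations are rebuilt
#' from the masks when available (exact foreground areas); otherwise from
#' the YOLO labels (box areas).
#'
#' @param dir dataset directory containing \code{manifest.yaml}.
#' @return A \linkS4class{SliceSet}.
#' @export
readSliceSet <- function(dir) {
    manifest <- file.path(dir, "manifest.yaml")
    if (!file.exists(manifest))
        stop(sprintf("no manifest.yaml under '%s'", dir))
    x <- yaml::read_yaml(manifest)
    readRaster <- function(path) {
        d <- EBImage::imageData(EBImage::readImage(path))
        matrix(as.numeric(d), dim(d)[1L], dim(d)[2L])
    }
    slices <- lapply(x$slices, function(e) {
        img <- round(readRaster(
            file.path(dir, "images", paste0(e$sliceId, ".png"))) * 255)
        mask <- NULL
        if (isTRUE(e$hasMask)) {
            mask <- (readRaster(
                file.path(dir, "masks", paste0(e$sliceId, ".png"))) > 0.5) * 1L
            nd <- nodulesFromMask(mask)
        } else {
            boxes <- readLabels(file.path(dir, "labels",
                                          paste0(e$sliceId, ".txt")),
                                c(e$width, e$height))
            nd <- if (nrow(boxes)) {
                w <- boxes$xmax - boxes$xmin
                h <- boxes$ymax - boxes$ymin
                data.frame(boxes[, c("xmin", "ymin", "xmax", "ymax")],
                           areaPx = w * h, aspectRatio = pmax(w / h, h / w))
            } else emptyNoduleFrame()
        }
        new("SliceRecord", sliceId = e$sliceId, patientId = e$patientId,
            image = img, spacingMm = e$spacingMm, nodules = nd,
            mask = mask, lungMask = NULL, quality = NULL)
    })
    new("SliceSet", slices = slices)
}

#' Write / read detection summaries as JSON
#'
#' Detector-agnostic prediction interchange: one JSON record per slice
#' with fields \code{sliceId}, \code{boxes} (array of
#' \code{[xmin, ymin, xmax, ymax]}), \code{confidences},
#' \code{preNmsScores} and \code{nGt}.
#'
#' @param summaries list of \linkS4class{DetectionSummary}.
#' @param path JSON file path.
#' @return \code{writePredictions}: the path, invisibly;
#'   \code{readPredictions}: a list of \linkS4class{DetectionSummary}.
#' @export
writePredictions <- function(summaries, path) {
    recs <- lapply(summaries, function(s) list(
        sliceId = s@sliceId,
        boxes = unname(apply(as.matrix(
            s@boxes[, c("xmin", "ymin", "xmax", "ymax"), drop = FALSE]),
            1L, as.numeric, simplify = FALSE)),
        confidences = as.numeric(s@confidences),
        preNmsScores = as.numeric(s@preNmsScores),
        nGt = s@nGt))
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writePredictions
#' @export
readPredictions <- function(path) {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(recs, function(r) {
        b <- if (length(r$boxes))
            as.data.frame(do.call(rbind, lapply(r$boxes, unlist)))
        else data.frame(matrix(numeric(0), 0L, 4L))
        names(b) <- c("xmin", "ymin", "xmax", "ymax")
        new("DetectionSummary", sliceId = r$sliceId, boxes = b,
            confidences = as.numeric(unlist(r$confidences)),
            preNmsScores = as.numeric(unlist(r$preNmsScores)),
            nGt = as.integer(r$nGt))
    })
}
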