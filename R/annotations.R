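#' Extract bounding boxes from a binary mask
#'
#' Labels the 8-connected foreground components of a binary segmentation
#' mask and returns the tight axis-aligned bounding box of each component
#' under the package's 0-based, half-open convention
#' (\code{[xmin, xmax) x [ymin, ymax)}, x = column, y = row).
#'
#' Component labelling is delegated to \code{EBImage::bwlabel}, which uses
#' 4-connectivity; labels that touch diagonally are merged afterwards so
#' that the result is 8-connected, the standard convention for blob
#' labelling.
#'
#' @param mask binary matrix (values 0/1 or logical).
#' @return data.frame with columns \code{xmin, ymin, xmax, ymax}, one row
#'   per component, ordered by first foreground pixel in column-major order.
#' @examples
#' m <- matrix(0, 8, 8); m[3:4, 5:6] <- 1
#' maskToBoxes(m)
#' @export
maskToBoxes <- function(mask) {
    if (is.logical(mask)) mask <- mask * 1L
    u <- unique(as.vector(mask))
    if (!all(u %in% c(0, 1)))
        stop("mask must be binary (0/1)")
    if (!any(mask == 1)) {
        return(data.frame(xmin = numeric(0), ymin = numeric(0),
                          xmax = numeric(0), ymax = numeric(0)))
    }
    lab <- EBImage::bwlabel(mask)
    lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
    lab <- merge8Connected(lab)
    ids <- setdiff(sort(unique(as.vector(lab))), 0L)
    out <- lapply(ids, function(id) {
        idx <- which(lab == id, arr.ind = TRUE)
        tightBox(idx[, 1L], idx[, 2L])
    })
    as.data.frame(do.call(rbind, out))
}

# Merge 4-connected labels that are diagonal neighbours (union-find), so
# the labelling is effectively 8-connected.
merge8Connected <- function(lab) {
    nr <- nrow(lab); nc <- ncol(lab)
    pairs <- rbind(
        cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),  # down-right
        cbind(as.vector(lab[-1L, -nc]), as.vector(lab[-nr, -1L]))   # up-right
    )
    pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
    if (!nrow(pairs)) return(lab)
    n <- max(lab)
    parent <- seq_len(n)
    find <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1L]); b <- find(pairs[k, 2L])
        if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(n), find, integer(1))
    # compact to consecutive ids in order of appearance
    keep <- match(root, sort(unique(root)))
    pos <- lab > 0L
    lab[pos] <- keep[lab[pos]]
    lab
}

#' Read YOLO-format labels
#'
#' Parses a YOLO label text file (one row per box:
#' \code{class cx cy w h}, all four geometry values normalized to [0, 1])
#' and converts the boxes to pixel coordinates under the half-open
#' convention.
#'
#' @param path label file path; a missing or empty file yields zero boxes.
#' @param imageSize integer vector \code{c(width, height)} in pixels, or a
#'   scalar for square images.
#' @return data.frame with columns \code{class, xmin, ymin, xmax, ymax}.
#' @seealso \code{\link{writeLabels}}
#' @export
readLabels <- function(path, imageSize) {
    imageSize <- rep(as.numeric(imageSize), length.out = 2L)
    w <- imageSize[1L]; h <- imageSize[2L]
    empty <- data.frame(class = integer(0), xmin = numeric(0),
                        ymin = numeric(0), xmax = numeric(0),
                        ymax = numeric(0))
    if (!file.exists(path)) return(empty)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(empty)
    rows <- lapply(seq_along(lines), function(i) {
        f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
        vals <- suppressWarnings(as.numeric(f))
        if (length(f) != 5L || anyNA(vals))
            stop(sprintf("malformed label row %d in '%s': '%s'",
                         i, path, lines[i]))
        if (any(vals[2:5] < 0) || any(vals[2:5] > 1))
            stop(sprintf("label row %d in '%s': normalized values outside [0, 1]",
                         i, path))
        vals
    })
    m <- do.call(rbind, rows)
    data.frame(class = as.integer(m[, 1L]),
               xmin = (m[, 2L] - m[, 4L] / 2) * w,
               ymin = (m[, 3L] - m[, 5L] / 2) * h,
               xmax = (m[, 2L] + m[, 4L] / 2) * w,
               ymax = (m[, 3L] + m[, 5L] / 2) * h)
}

#' Write YOLO-format labels
#'
#' Normalizes pixel boxes to YOLO center-size format and writes one row per
#' box. Writing then reading recovers each coordinate to within 0.5 px
#' (quantization of the printed decimals).
#'
#' @param boxes data.frame with columns \code{xmin, ymin, xmax, ymax}
#'   (pixels, half-open); an optional \code{class} column (default 0, the
#'   single "nodule" class).
#' @param imageSize \code{c(width, height)} in pixels, or a scalar.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
writeLabels <- function(boxes, imageSize, path) {
    boxes <- asBoxFrame(boxes)
    imageSize <- rep(as.numeric(imageSize), length.out = 2L)
    w <- imageSize[1L]; h <- imageSize[2L]
    cls <- if ("class" %in% names(boxes)) boxes$class else rep(0L, nrow(boxes))
    if (nrow(boxes)) {
        cx <- (boxes$xmin + boxes$xmax) / 2 / w
        cy <- (boxes$ymin + boxes$ymax) / 2 / h
        bw <- (boxes$xmax - boxes$xmin) / w
        bh <- (boxes$ymax - boxes$ymin) / h
        lines <- sprintf("%d %.9f %.9f %.9f %.9f", cls, cx, cy, bw, bh)
    } else lines <- character(0)
    writeLines(lines, path)
    invisible(path)
}

#' Nodule diameter in millimetres
#'
#' The diameter of a nodule is defined as the larger of its bounding-box
#' width and height, converted to mm by the in-plane pixel spacing. This is
#' the quantity compared against the 3 mm clinical-relevance cutoff
#' (\code{\link{filterSmallNodules}}; the filter is strictly "< 3 mm", so a
#' 3.0 mm nodule is retained).
#'
#' @param box data.frame (or one-row slice) with \code{xmin, ymin, xmax,
#'   ymax} in pixels; vectorized over rows.
#' @param spacingMm pixel spacing in mm/pixel, > 0.
#' @return Numeric vector of diameters in mm.
#' @examples
#' noduleDiameterMm(data.frame(xmin = 0, ymin = 0, xmax = 10, ymax = 6), 0.5)
#' @export
noduleDiameterMm <- function(box, spacingMm) {
    stopifnot(is.numeric(spacingMm), length(spacingMm) == 1L, spacingMm > 0)
    box <- asBoxFrame(box)
    pmax(box$xmax - box$xmin, box$ymax - box$ymin) * spacingMm
}

#' Derive nodule annotations from a segmentation mask
#'
#' Combines \code{\link{maskToBoxes}} with per-component foreground counts
#' and box aspect ratios to build the \code{nodules} annotation frame of a
#' \linkS4class{SliceRecord}: \code{areaPx} is the exact mask foreground
#' pixel count of the component and \code{aspectRatio} is
#' \code{max(w/h, h/w)} of its tight box.
#'
#' @param mask binary matrix.
#' @return data.frame with columns \code{xmin, ymin, xmax, ymax, areaPx,
#'   aspectRatio}.
#' @export
nodulesFromMask <- function(mask) {
    boxes <- maskToBoxes(mask)
    if (!nrow(boxes)) return(emptyNoduleFrame())
    if (is.logical(mask)) mask <- mask * 1L
    lab <- merge8Connected(
        matrix(as.integer(EBImage::bwlabel(mask)), nrow(mask), ncol(mask)))
    counts <- tabulate(lab[lab > 0L])
    w <- boxes$xmax - boxes$xmin
    h <- boxes$ymax - boxes$ymin
    data.frame(boxes, areaPx = counts[seq_len(nrow(boxes))],
               aspectRatio = pmax(w / h, h / w))
}
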