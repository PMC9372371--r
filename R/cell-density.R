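# Automated counting of dark-stained somata in Nissl micrographs.
# Classical pipeline: invert (stain is dark), background flattening, global
# threshold (Otsu by default), binary opening, connected components, area
# filter, optional distance-transform watershed split of touching blobs.

#' Count cells in a Nissl micrograph and convert to density
#'
#' @param img a \linkS4class{Micrograph}.
#' @param roi logical matrix with the region of interest; defaults to the
#'   whole frame.
#' @param threshold 8-bit threshold on the inverted, flattened image, or
#'   \code{"auto"} (Otsu within the ROI).
#' @param areaBounds numeric length-2, admissible object area in um^2;
#'   objects outside the interval are discarded (sub-nuclear debris below,
#'   clumps/artefacts above). Default c(7, 700).
#' @param splitTouching logical; split touching blobs by a
#'   distance-transform watershed.
#' @param flattenSigma Gaussian SD in pixels for background flattening
#'   (subtraction of a heavily smoothed copy); 0 disables.
#' @param openingSize odd integer, binary opening brush size in pixels;
#'   0 disables.
#' @return list of class \code{CellCountResult}: \code{count},
#'   \code{roiArea} (um^2), \code{CD} (cells/mm^2), \code{centers}
#'   (data.frame row/col), \code{labels} (integer matrix of accepted
#'   objects).
#' @export
countCells <- function(img, roi = NULL, threshold = "auto",
                       areaBounds = c(7, 700), splitTouching = TRUE,
                       flattenSigma = 25, openingSize = 3) {
  stopifnot(is(img, "Micrograph"))
  px <- pixels(img)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(px), ncol(px))
  if (!identical(dim(roi), dim(px))) stop("ROI mask outside image bounds")
  roi <- as.logical(roi); dim(roi) <- dim(px)
  if (!any(roi)) stop("empty ROI")
  if (!identical(threshold, "auto") &&
      (threshold < 0 || threshold > 255))
    stop("threshold outside [0, 255]")

  inv <- 255 - px
  if (flattenSigma > 0) {
    bg <- convolveReflect(inv, gaussianKernel2d(flattenSigma,
      size = min(2L * ceiling(2.5 * flattenSigma) + 1L,
                 2L * (min(dim(inv)) %/% 2L) - 1L)))
    inv <- pmax(inv - bg, 0)
  }
  thr <- if (identical(threshold, "auto")) {
    v <- inv[roi]
    if (max(v) == min(v)) Inf else
      EBImage::otsu(EBImage::Image(matrix(v / 255, ncol = 1)),
                    range = c(0, 1)) * 255
  } else threshold
  bin <- (inv > thr) & roi
  if (openingSize >= 3) {
    k <- EBImage::makeBrush(openingSize, shape = "disc")
    bin <- EBImage::opening(bin * 1, k) > 0
  }
  labels <- if (splitTouching && any(bin)) {
    dm <- EBImage::distmap(EBImage::Image(bin * 1))
    EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin * 1)))
  }
  pxArea <- pixelSize(img)^2  # um^2 per pixel
  keepCenters <- NULL
  if (max(labels) > 0) {
    tab <- tabulate(labels[labels > 0])
    areas <- tab * pxArea
    keep <- which(areas >= areaBounds[1] & areas <= areaBounds[2])
    labels[!(labels %in% keep)] <- 0L
    if (length(keep)) {
      idx <- which(labels > 0, arr.ind = TRUE)
      lab <- labels[labels > 0]
      cr <- vapply(split(idx[, 1], lab), mean, numeric(1))
      cc <- vapply(split(idx[, 2], lab), mean, numeric(1))
      inRoi <- roi[cbind(round(cr), round(cc))]
      keepCenters <- data.frame(row = cr[inRoi], col = cc[inRoi])
    }
  }
  if (is.null(keepCenters))
    keepCenters <- data.frame(row = numeric(0), col = numeric(0))
  roiArea <- sum(roi) * pxArea
  out <- list(count = nrow(keepCenters), roiArea = roiArea,
              CD = nrow(keepCenters) / roiArea * 1e6,  # per mm^2
              centers = keepCenters, labels = labels,
              threshold = thr)
  class(out) <- "CellCountResult"
  out
}

#' @export
print.CellCountResult <- function(x, ...) {
  cat(sprintf("CellCountResult: %d cells in %.1f um^2 (CD = %.1f /mm^2)\n",
              x$count, x$roiArea, x$CD))
  invisible(x)
}
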