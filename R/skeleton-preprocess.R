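# GFAP preprocessing cascade producing the binary image that is thinned.
# Ordered stages: bandpass (difference of Gaussians), rolling-ball
# background subtraction, brightness/contrast rescale, unsharp mask,
# despeckle, threshold window (stain is dark), binary despeckle + closing +
# remove-outliers.

#' Skeletonization configuration
#'
#' Defaults follow the astrocyte-process workflow for high-magnification
#' GFAP tiles: bandpass passing structures between 3 and 40 px, rolling
#' ball radius 200 px, brightness/contrast rescale of [10, 254] to
#' [0, 255], unsharp mask sigma 1.5 px with weight 0.6, and region-specific
#' upper threshold levels (corpus callosum 218, layer V 223, layer VI 219,
#' CA3b 223). \code{fragmentCutoff} is the minimum surviving skeleton
#' component length, 0.7 um.
#'
#' @param bandpassLarge,bandpassSmall structure-size bounds in pixels.
#' @param rollingBallRadius background-subtraction radius in pixels.
#' @param rescaleMin,rescaleMax input range mapped to [0, 255].
#' @param unsharpSigma,unsharpWeight unsharp-mask parameters.
#' @param thresholdUpper 8-bit upper threshold (foreground = value <=
#'   threshold); selected via \code{region} when NULL.
#' @param region one of "cc", "layerV", "layerVI", "CA3b"; sets
#'   \code{thresholdUpper} when that is NULL.
#' @param outlierRadius,outlierThreshold remove-outliers parameters
#'   (median-deviation filter), pixels / 8-bit levels.
#' @param fragmentCutoff um, small-fragment filter cutoff.
#' @return list of class \code{SkeletonConfig}.
#' @export
skeletonConfig <- function(bandpassLarge = 40, bandpassSmall = 3,
                           rollingBallRadius = 200,
                           rescaleMin = 10, rescaleMax = 254,
                           unsharpSigma = 1.5, unsharpWeight = 0.6,
                           thresholdUpper = NULL, region = "CA3b",
                           outlierRadius = 2, outlierThreshold = 50,
                           fragmentCutoff = 0.7) {
  regionThresholds <- c(cc = 218, layerV = 223, layerVI = 219, CA3b = 223)
  if (is.null(thresholdUpper)) {
    if (!region %in% names(regionThresholds))
      stop("unknown region: ", region)
    thresholdUpper <- regionThresholds[[region]]
  }
  stopifnot(thresholdUpper >= 0, thresholdUpper <= 255,
            fragmentCutoff > 0, bandpassLarge > bandpassSmall,
            unsharpWeight > 0, unsharpWeight < 1)
  structure(list(bandpassLarge = bandpassLarge,
                 bandpassSmall = bandpassSmall,
                 rollingBallRadius = rollingBallRadius,
                 rescaleMin = rescaleMin, rescaleMax = rescaleMax,
                 unsharpSigma = unsharpSigma,
                 unsharpWeight = unsharpWeight,
                 thresholdUpper = thresholdUpper, region = region,
                 outlierRadius = outlierRadius,
                 outlierThreshold = outlierThreshold,
                 fragmentCutoff = fragmentCutoff),
            class = "SkeletonConfig")
}

# Grayscale erosion/dilation with a disc structuring element, via running
# min/max over the disc offsets (borders behave as if padded by +/-Inf).
grayMorph <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  fill <- if (op == "erode") Inf else -Inf
  agg <- if (op == "erode") pmin else pmax
  out <- m
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr == 0 && dc == 0) next
    if (dr^2 + dc^2 > radius^2 + 1e-9) next
    out <- agg(out, shiftMatrix(m, dr, dc, fill = fill))
  }
  out
}

# Rolling-ball style background estimate: grayscale opening with a disc.
# For large radii the image is opened at reduced scale and resized back,
# the usual shortcut for big structuring elements.
rollingBallBackground <- function(m, radius) {
  if (radius <= 0) return(matrix(0, nrow(m), ncol(m)))
  shrink <- max(1L, floor(radius / 16))
  small <- if (shrink > 1L) {
    EBImage::imageData(EBImage::resize(EBImage::Image(m),
      w = max(8L, nrow(m) %/% shrink), h = max(8L, ncol(m) %/% shrink)))
  } else m
  r <- max(1L, min(round(radius / shrink), min(dim(small)) - 1L))
  op <- grayMorph(grayMorph(small, r, "erode"), r, "dilate")
  if (shrink > 1L) {
    op <- EBImage::imageData(EBImage::resize(EBImage::Image(op),
      w = nrow(m), h = ncol(m)))
  }
  op
}

# Median-deviation outlier removal: replace a pixel by the local median
# when it deviates from it by more than `threshold` in direction `bright`.
removeOutliers <- function(m, radius = 2, threshold = 50,
                           direction = c("bright", "dark")) {
  direction <- match.arg(direction)
  med <- EBImage::imageData(EBImage::medianFilter(
    EBImage::Image(m / 255), size = max(1L, as.integer(radius)))) * 255
  dev <- if (direction == "bright") m - med else med - m
  out <- m
  out[dev > threshold] <- med[dev > threshold]
  out
}

#' Preprocess a GFAP micrograph to a binary image
#'
#' Runs the ordered cascade described in \code{\link{skeletonConfig}}.
#' Stained structures are dark, so thresholding keeps pixels at or below
#' \code{thresholdUpper} (an inclusive [0, upper] intensity window).
#'
#' @param img a \linkS4class{Micrograph}.
#' @param cfg a \code{\link{skeletonConfig}}.
#' @return logical matrix: the binary (foreground = stained process) image.
#' @export
preprocessGfap <- function(img, cfg = skeletonConfig()) {
  stopifnot(is(img, "Micrograph"))
  m <- pixels(img)
  # 1. bandpass: difference of Gaussians keeping structures between
  #    bandpassSmall and bandpassLarge px (sigma = size / 2)
  sSmall <- cfg$bandpassSmall / 2
  sLarge <- cfg$bandpassLarge / 2
  capSize <- function(sigma) {
    min(2L * ceiling(3 * sigma) + 1L, 2L * (min(dim(m)) %/% 2L) - 1L)
  }
  bp <- convolveReflect(m, gaussianKernel2d(sSmall, capSize(sSmall))) -
        convolveReflect(m, gaussianKernel2d(sLarge, capSize(sLarge)))
  # restore the DC level so the dark-stain-on-bright-ground polarity that
  # the threshold windows assume is preserved
  m <- bp + mean(m)
  m[m < 0] <- 0; m[m > 255] <- 255
  # 2. rolling-ball background subtraction (background is bright; subtract
  #    the opening of the inverted image from the inverted image, then
  #    re-invert so stain stays dark)
  inv <- 255 - m
  inv <- inv - rollingBallBackground(inv, cfg$rollingBallRadius)
  inv[inv < 0] <- 0
  m <- 255 - inv
  # 3. brightness/contrast: map [rescaleMin, rescaleMax] -> [0, 255], clip
  m <- (m - cfg$rescaleMin) / (cfg$rescaleMax - cfg$rescaleMin) * 255
  m[m < 0] <- 0; m[m > 255] <- 255
  # 4. unsharp mask: (I - w G(I)) / (1 - w)
  g <- convolveReflect(m, gaussianKernel2d(cfg$unsharpSigma))
  m <- (m - cfg$unsharpWeight * g) / (1 - cfg$unsharpWeight)
  m[m < 0] <- 0; m[m > 255] <- 255
  # 5. despeckle (3x3 median)
  m <- EBImage::imageData(EBImage::medianFilter(
    EBImage::Image(m / 255), size = 1L)) * 255
  # 6. threshold window [0, upper]; stain dark
  bin <- m <= cfg$thresholdUpper
  # 7. binary cleanup: despeckle, close, remove outliers
  b <- bin * 255
  b <- EBImage::imageData(EBImage::medianFilter(
    EBImage::Image(b / 255), size = 1L)) * 255
  b <- EBImage::imageData(EBImage::closing(EBImage::Image(b / 255),
    EBImage::makeBrush(3, shape = "box"))) * 255
  b <- removeOutliers(b, cfg$outlierRadius, cfg$outlierThreshold,
                      direction = "bright")
  b > 127
}
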