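# Pixelwise 2D structure-tensor analysis. Image gradients are taken with
# truncated Gaussian-derivative kernels (default size 11 px, sigma 3 px);
# the raw gradient outer products are then window-integrated with a
# Gaussian, giving a positive semi-definite 2x2 tensor per pixel.

#' Structure-tensor configuration
#'
#' @param derivativeSigma Gaussian-derivative SD in pixels (default 3).
#' @param kernelSize odd kernel size in pixels (default 11).
#' @param integrationSigma Gaussian integration-window SD in pixels;
#'   defaults to \code{derivativeSigma}.
#' @param traceFloor fraction of the maximum tensor trace below which a
#'   pixel is considered flat and excluded (default 1e-6).
#' @param traceFloorAbs absolute trace floor in squared 8-bit gradient
#'   units; guards against numerically flat images (default 1e-9).
#' @return list of class \code{StConfig}.
#' @export
stConfig <- function(derivativeSigma = 3, kernelSize = 11,
                     integrationSigma = derivativeSigma,
                     traceFloor = 1e-6, traceFloorAbs = 1e-9) {
  stopifnot(kernelSize %% 2 == 1, derivativeSigma > 0,
            integrationSigma > 0, traceFloor >= 0, traceFloorAbs >= 0)
  structure(list(derivativeSigma = derivativeSigma,
                 kernelSize = as.integer(kernelSize),
                 integrationSigma = integrationSigma,
                 traceFloor = traceFloor, traceFloorAbs = traceFloorAbs),
            class = "StConfig")
}

#' Compute the pixelwise structure-tensor field of a micrograph
#'
#' Convolves the image with directional derivatives of a 2D Gaussian in the
#' row and column directions, forms the per-pixel gradient outer product,
#' and integrates it with a Gaussian window. Boundaries are handled by
#' reflect padding so no spurious edge gradients arise.
#'
#' @param img a \linkS4class{Micrograph} (or plain numeric matrix).
#' @param cfg a \code{\link{stConfig}}.
#' @return A \linkS4class{StructureTensorField}.
#' @export
structureTensorField <- function(img, cfg = stConfig()) {
  m <- if (is(img, "Micrograph")) pixels(img) else img
  if (any(dim(m) < cfg$kernelSize))
    stop("image smaller than the derivative kernel")
  g <- gaussian1d(cfg$kernelSize, cfg$derivativeSigma)
  gd <- gaussian1d(cfg$kernelSize, cfg$derivativeSigma, deriv = TRUE)
  # separable kernels: rows = y, columns = x
  Ky <- outer(gd, g)   # derivative along rows
  Kx <- outer(g, gd)   # derivative along columns
  Iy <- convolveReflect(m, Ky)
  Ix <- convolveReflect(m, Kx)
  W <- gaussianKernel2d(cfg$integrationSigma)
  new("StructureTensorField",
      Jxx = convolveReflect(Ix * Ix, W),
      Jxy = convolveReflect(Ix * Iy, W),
      Jyy = convolveReflect(Iy * Iy, W),
      config = unclass(cfg))
}

#' Anisotropy index from a structure-tensor field
#'
#' Per-pixel anisotropy is the normalised eigenvalue difference
#' \eqn{AI = (\mu_1 - \mu_2) / (\mu_1 + \mu_2)} of the 2x2 tensor, bounded
#' in [0, 1]; pixels whose trace falls at or below
#' \code{traceFloor * max(trace)} are treated as flat and excluded. The ROI
#' value is the mean of per-pixel AI over valid ROI pixels
#' (\code{aggregate = "mean"}); \code{aggregate = "tensor"} instead sums
#' the tensor over the ROI and reports the AI of the summed tensor, for
#' sensitivity checks.
#'
#' @param field a \linkS4class{StructureTensorField}.
#' @param roi logical matrix; defaults to the whole field.
#' @param cfg a \code{\link{stConfig}} (supplies \code{traceFloor}).
#' @param aggregate \code{"mean"} (default) or \code{"tensor"}.
#' @return list of class \code{AnisotropyResult}: \code{AI},
#'   \code{perPixelAI} (matrix, NA where invalid), \code{nValidPixels}.
#' @export
anisotropyIndex <- function(field, roi = NULL, cfg = stConfig(),
                            aggregate = c("mean", "tensor")) {
  stopifnot(is(field, "StructureTensorField"))
  aggregate <- match.arg(aggregate)
  Jxx <- field@Jxx; Jxy <- field@Jxy; Jyy <- field@Jyy
  if (is.null(roi)) roi <- matrix(TRUE, nrow(Jxx), ncol(Jxx))
  if (!identical(dim(roi), dim(Jxx))) stop("ROI outside field")
  roi <- as.logical(roi); dim(roi) <- dim(Jxx)
  tr <- Jxx + Jyy
  valid <- roi & (tr > max(cfg$traceFloor * max(tr), cfg$traceFloorAbs))
  if (!any(valid))
    stop("no valid pixels in ROI: region is flat")
  gap <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  perPixel <- matrix(NA_real_, nrow(Jxx), ncol(Jxx))
  perPixel[valid] <- gap[valid] / tr[valid]
  AI <- if (aggregate == "mean") {
    mean(perPixel[valid])
  } else {
    sx <- sum(Jxx[valid]); sy <- sum(Jyy[valid]); sxy <- sum(Jxy[valid])
    sqrt((sx - sy)^2 + 4 * sxy^2) / (sx + sy)
  }
  structure(list(AI = AI, perPixelAI = perPixel,
                 nValidPixels = sum(valid)),
            class = "AnisotropyResult")
}

#' @export
print.AnisotropyResult <- function(x, ...) {
  cat(sprintf("AnisotropyResult: AI = %.4f over %d valid pixels\n",
              x$AI, x$nValidPixels))
  invisible(x)
}

#' ROI anisotropy index of a micrograph in one call
#'
#' Convenience wrapper: structure-tensor field plus
#' \code{\link{anisotropyIndex}}.
#'
#' @inheritParams structureTensorField
#' @inheritParams anisotropyIndex
#' @return see \code{\link{anisotropyIndex}}.
#' @export
micrographAI <- function(img, roi = NULL, cfg = stConfig(),
                         aggregate = c("mean", "tensor")) {
  anisotropyIndex(structureTensorField(img, cfg), roi, cfg, aggregate)
}
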