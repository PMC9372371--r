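# Shared fixture builders, all generated in code.

quantize8 <- dtihisto:::quantize8

# Sinusoidal grating micrograph; vertical = TRUE varies along columns.
makeGrating <- function(n = 128, period = 8, amplitude = 100,
                        vertical = TRUE, pixelSize = 1) {
  X <- matrix(rep(seq_len(n), each = n), n, n)  # column index
  if (!vertical) X <- t(X)
  Micrograph(quantize8(127 + amplitude * sin(2 * pi * X / period)),
             pixelSize)
}

# Superposition of two orthogonal gratings of equal amplitude.
makeCrossGrating <- function(n = 128, period = 8, amplitude = 50) {
  X <- matrix(rep(seq_len(n), each = n), n, n)
  Micrograph(quantize8(127 + amplitude * sin(2 * pi * X / period) +
                       amplitude * sin(2 * pi * t(X) / period)), 1)
}

# Image with dark anti-aliased disks at given centres/radii on bright bg.
makeDiskImage <- function(centers, radii, n = 64, fg = 60, bg = 200,
                          pixelSize = 1) {
  img <- matrix(bg, n, n)
  for (i in seq_len(nrow(centers))) {
    st <- dtihisto:::diskStamp(centers[i, 1], centers[i, 2], radii[i], n, n)
    img[st$idx] <- pmin(img[st$idx], bg + (fg - bg) * st$alpha)
  }
  Micrograph(quantize8(img), pixelSize)
}

# Boundary-tolerant agreement between two masks: fraction of each mask
# within one pixel of the other.
maskAgreement <- function(a, b) {
  dil <- function(m) EBImage::dilate(m * 1, EBImage::makeBrush(3, "box")) > 0
  c(precision = sum(a & dil(b)) / max(1, sum(a)),
    recall = sum(b & dil(a)) / max(1, sum(b)))
}

# Compare measured skeleton metrics to phantom ground truth.
topologyMatches <- function(metrics, truth) {
  metrics$branches == truth$branches &&
    metrics$junctions == truth$junctions &&
    metrics$endpointVoxels == truth$endpoints &&
    metrics$triplePoints == truth$triplePoints &&
    metrics$quadruplePoints == truth$quadruplePoints
}
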