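# Phantom generators: synthetic micrographs with exact ground truth, used to
# exercise every image-quantification stage without real data. Stained
# structures are dark on a bright background, as in brightfield histology.

#' Specification for a Nissl-like cell phantom
#'
#' Dark circular somata at known density on a bright background, emulating a
#' Nissl-stained micrograph for automated cell counting.
#'
#' @param imageSize integer, image edge in pixels (square image).
#' @param pixelSize um per pixel.
#' @param nCells number of cells to place.
#' @param cellRadiusRange um interval for cell radii (uniform draw).
#' @param cellIntensity,backgroundIntensity 8-bit levels; cells darker.
#' @param noiseSd additive Gaussian noise SD, 8-bit levels.
#' @param minCenterDistance minimum centre-to-centre distance in um;
#'   defaults to twice the maximum radius plus one pixel so cells never
#'   touch. Set smaller (with \code{allowTouching = TRUE}) to exercise the
#'   watershed splitting path of the counter.
#' @param allowTouching logical; permit overlapping placements.
#' @param seed integer seed.
#' @return A list of class \code{NisslPhantomSpec}.
#' @export
nisslPhantomSpec <- function(imageSize = 256, pixelSize = 1, nCells = 50,
                             cellRadiusRange = c(3, 5),
                             cellIntensity = 60, backgroundIntensity = 200,
                             noiseSd = 0, minCenterDistance = NULL,
                             allowTouching = FALSE, seed = 1) {
  if (is.null(minCenterDistance))
    minCenterDistance <- 2 * max(cellRadiusRange) + pixelSize
  spec <- list(imageSize = as.integer(imageSize), pixelSize = pixelSize,
               nCells = as.integer(nCells),
               cellRadiusRange = cellRadiusRange,
               cellIntensity = cellIntensity,
               backgroundIntensity = backgroundIntensity,
               noiseSd = noiseSd, minCenterDistance = minCenterDistance,
               allowTouching = isTRUE(allowTouching), seed = seed)
  stopifnot(spec$nCells >= 0, spec$cellIntensity < spec$backgroundIntensity,
            all(spec$cellRadiusRange > 0), spec$pixelSize > 0,
            spec$noiseSd >= 0)
  class(spec) <- "NisslPhantomSpec"
  spec
}

#' Generate a Nissl-like cell phantom
#'
#' Places \code{nCells} non-overlapping (by default) dark disks with a
#' one-pixel anti-aliased rim, adds Gaussian noise, and quantises to 8 bits.
#' The ground truth records exact centres, radii, and the ideal binary mask.
#'
#' @param spec a \code{\link{nisslPhantomSpec}}.
#' @return list with elements \code{image} (\linkS4class{Micrograph}) and
#'   \code{truth} (list: \code{centers} data.frame with row/col/radius_um,
#'   \code{count}, \code{mask} logical matrix of the ideal cells).
#' @export
generateNissl <- function(spec) {
  stopifnot(inherits(spec, "NisslPhantomSpec"))
  n <- spec$imageSize
  withr::with_seed(streamSeed(spec$seed, 101L), {
    centers <- placePoints(spec$nCells, n, n,
                           minDistPx = spec$minCenterDistance / spec$pixelSize,
                           marginPx = max(spec$cellRadiusRange) / spec$pixelSize + 1,
                           allowTouching = spec$allowTouching)
    radii <- runif(spec$nCells, spec$cellRadiusRange[1],
                   spec$cellRadiusRange[2])
    img <- matrix(spec$backgroundIntensity, n, n)
    mask <- matrix(FALSE, n, n)
    if (spec$nCells > 0) {
      for (i in seq_len(spec$nCells)) {
        rpx <- radii[i] / spec$pixelSize
        stamp <- diskStamp(centers[i, 1], centers[i, 2], rpx, n, n)
        # alpha-composite the dark disk over the background
        img[stamp$idx] <- pmin(img[stamp$idx],
          spec$backgroundIntensity +
            (spec$cellIntensity - spec$backgroundIntensity) * stamp$alpha)
        mask[stamp$idx[stamp$alpha >= 0.5, , drop = FALSE]] <- TRUE
      }
    }
    if (spec$noiseSd > 0)
      img <- img + rnorm(length(img), 0, spec$noiseSd)
    list(image = Micrograph(quantize8(img), spec$pixelSize),
         truth = list(
           centers = data.frame(row = centers[, 1], col = centers[, 2],
                                radius_um = radii),
           count = spec$nCells, mask = mask))
  })
}

# Rejection-sample point placements with a minimum pairwise distance.
placePoints <- function(n, nr, nc, minDistPx, marginPx, allowTouching,
                        maxTries = 4000L) {
  pts <- matrix(numeric(0), 0, 2)
  if (n == 0) return(pts)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > maxTries * n)
      stop("could not place ", n, " points: spec is overcrowded")
    cand <- c(runif(1, 1 + marginPx, nr - marginPx),
              runif(1, 1 + marginPx, nc - marginPx))
    if (!allowTouching && nrow(pts) > 0) {
      d2 <- (pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2
      if (min(d2) < minDistPx^2) next
    }
    pts <- rbind(pts, cand)
  }
  pts
}

# Anti-aliased disk footprint: indices plus coverage alpha in [0,1].
diskStamp <- function(r0, c0, radiusPx, nr, nc) {
  rr <- max(1L, floor(r0 - radiusPx - 1)):min(nr, ceiling(r0 + radiusPx + 1))
  cc <- max(1L, floor(c0 - radiusPx - 1)):min(nc, ceiling(c0 + radiusPx + 1))
  g <- expand.grid(row = rr, col = cc)
  d <- sqrt((g$row - r0)^2 + (g$col - c0)^2)
  alpha <- pmin(1, pmax(0, radiusPx + 0.5 - d))
  keep <- alpha > 0
  list(idx = cbind(g$row[keep], g$col[keep]), alpha = alpha[keep])
}

#' Specification for an oriented fiber-texture phantom
#'
#' Dark line segments whose orientations are drawn from a von Mises
#' distribution on the axial circle; emulates myelin- or GFAP-stained
#' texture for structure-tensor analysis. \code{dispersionKappa = 0} gives
#' uniformly distributed orientations; large kappa gives nearly parallel
#' fibers.
#'
#' @param imageSize image edge in pixels.
#' @param pixelSize um per pixel.
#' @param meanOrientation radians, mean fiber orientation (axial, mod pi).
#' @param dispersionKappa von Mises concentration, >= 0.
#' @param nFibers number of segments.
#' @param fiberWidth um, full width of each fiber.
#' @param fiberLength um, segment length (constant).
#' @param fiberIntensity,backgroundIntensity 8-bit levels.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return A list of class \code{FiberPhantomSpec}.
#' @export
fiberPhantomSpec <- function(imageSize = 256, pixelSize = 1,
                             meanOrientation = 0, dispersionKappa = 8,
                             nFibers = 120, fiberWidth = 2,
                             fiberLength = NULL,
                             fiberIntensity = 60, backgroundIntensity = 200,
                             noiseSd = 0, seed = 1) {
  if (is.null(fiberLength)) fiberLength <- 0.6 * imageSize * pixelSize
  spec <- list(imageSize = as.integer(imageSize), pixelSize = pixelSize,
               meanOrientation = meanOrientation,
               dispersionKappa = dispersionKappa,
               nFibers = as.integer(nFibers), fiberWidth = fiberWidth,
               fiberLength = fiberLength, fiberIntensity = fiberIntensity,
               backgroundIntensity = backgroundIntensity,
               noiseSd = noiseSd, seed = seed)
  stopifnot(spec$dispersionKappa >= 0, spec$nFibers >= 0,
            spec$fiberWidth > 0, spec$pixelSize > 0)
  class(spec) <- "FiberPhantomSpec"
  spec
}

# Concentrations above this cap are treated as "all parallel".
.KAPPA_CAP <- 500

#' Generate an oriented fiber-texture phantom
#'
#' Renders anti-aliased dark segments, composes them by intensity minimum,
#' adds noise, and quantises to 8 bits. Ground truth records the drawn
#' orientations and their axial circular variance.
#'
#' @param spec a \code{\link{fiberPhantomSpec}}.
#' @return list with \code{image} (\linkS4class{Micrograph}) and
#'   \code{truth} (list: \code{orientations} radians,
#'   \code{circularVariance}).
#' @export
generateFibers <- function(spec) {
  stopifnot(inherits(spec, "FiberPhantomSpec"))
  n <- spec$imageSize
  withr::with_seed(streamSeed(spec$seed, 202L), {
    if (spec$nFibers > 0) {
      if (spec$dispersionKappa >= .KAPPA_CAP) {
        theta <- rep(spec$meanOrientation, spec$nFibers)
      } else {
        # axial orientations: von Mises on doubled angles, then halved
        theta <- rvonmises(spec$nFibers, 2 * spec$meanOrientation,
                           spec$dispersionKappa) / 2
      }
    } else theta <- numeric(0)
    img <- matrix(spec$backgroundIntensity, n, n)
    halfLenPx <- spec$fiberLength / spec$pixelSize / 2
    halfWidPx <- spec$fiberWidth / spec$pixelSize / 2
    for (i in seq_along(theta)) {
      ctr <- runif(2, 1, n)
      # orientation theta: angle against the column (x) axis in image plane
      dvec <- c(-sin(theta[i]), cos(theta[i]))  # (drow, dcol)
      p0 <- ctr - halfLenPx * dvec
      p1 <- ctr + halfLenPx * dvec
      img <- stampSegment(img, p0, p1, halfWidPx,
                          spec$fiberIntensity, spec$backgroundIntensity)
    }
    if (spec$noiseSd > 0)
      img <- img + rnorm(length(img), 0, spec$noiseSd)
    list(image = Micrograph(quantize8(img), spec$pixelSize),
         truth = list(orientations = theta,
                      circularVariance = circularVarianceAxial(theta)))
  })
}

# Anti-aliased thick segment: intensity ramps over one pixel at the edge.
stampSegment <- function(img, p0, p1, halfWidPx, fg, bg) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- ceiling(halfWidPx + 1)
  rr <- max(1L, floor(min(p0[1], p1[1]) - pad)):
        min(nr, ceiling(max(p0[1], p1[1]) + pad))
  cc <- max(1L, floor(min(p0[2], p1[2]) - pad)):
        min(nc, ceiling(max(p0[2], p1[2]) + pad))
  if (!length(rr) || !length(cc)) return(img)
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  v <- p1 - p0
  len2 <- sum(v^2)
  t <- pmin(1, pmax(0, ((R - p0[1]) * v[1] + (C - p0[2]) * v[2]) / len2))
  d <- sqrt((R - (p0[1] + t * v[1]))^2 + (C - (p0[2] + t * v[2]))^2)
  alpha <- pmin(1, pmax(0, halfWidPx + 0.5 - d))
  sub <- img[rr, cc, drop = FALSE]
  img[rr, cc] <- pmin(sub, bg + (fg - bg) * alpha)
  img
}

#' Specification for a branching astrocyte phantom
#'
#' Disjoint tree-shaped structures with exactly known skeleton topology:
#' each tree has \code{branchesPerSoma} primary processes radiating from a
#' soma at distinct compass angles (multiples of 45 degrees), optionally
#' bifurcating once (\code{branchingDepth = 2}). The one-pixel centreline is
#' stamped with 8-connected Bresenham segments, then dilated to
#' \code{processWidth}, so the ground-truth skeleton is unambiguous.
#'
#' @param imageSize image edge in pixels.
#' @param pixelSize um per pixel (default 0.114, high-magnification tiles).
#' @param nSomata number of trees.
#' @param branchesPerSoma primary branches per tree (3 or 4; 3 gives a
#'   triple point at the soma, 4 a quadruple point).
#' @param branchLength um interval for primary branch lengths.
#' @param branchingDepth 1 (no bifurcation) or 2 (each primary process
#'   bifurcates at its tip into two child processes).
#' @param childLengthFrac child length as a fraction of its parent.
#' @param processWidth um, full width of the drawn processes.
#' @param nFragments number of planted isolated sub-cutoff fragments
#'   (short residues the 0.7 um filter must remove).
#' @param fragmentLength um interval for fragment centreline lengths; keep
#'   below the intended cutoff.
#' @param intensity,backgroundIntensity 8-bit levels.
#' @param noiseSd additive Gaussian noise SD.
#' @param seed integer seed.
#' @return A list of class \code{AstroPhantomSpec}.
#' @export
astroPhantomSpec <- function(imageSize = 300, pixelSize = 0.114,
                             nSomata = 3, branchesPerSoma = 3,
                             branchLength = c(2.3, 3.4),
                             branchingDepth = 1, childLengthFrac = 0.6,
                             processWidth = 0.342, nFragments = 0,
                             fragmentLength = c(0.3, 0.55),
                             intensity = 50, backgroundIntensity = 210,
                             noiseSd = 0, seed = 1) {
  spec <- list(imageSize = as.integer(imageSize), pixelSize = pixelSize,
               nSomata = as.integer(nSomata),
               branchesPerSoma = as.integer(branchesPerSoma),
               branchLength = branchLength,
               branchingDepth = as.integer(branchingDepth),
               childLengthFrac = childLengthFrac,
               processWidth = processWidth,
               nFragments = as.integer(nFragments),
               fragmentLength = fragmentLength,
               intensity = intensity,
               backgroundIntensity = backgroundIntensity,
               noiseSd = noiseSd, seed = seed)
  stopifnot(spec$nSomata >= 0, spec$branchesPerSoma %in% 3:4,
            spec$branchingDepth %in% 1:2, all(spec$branchLength > 0),
            spec$processWidth > 0, spec$intensity < spec$backgroundIntensity)
  class(spec) <- "AstroPhantomSpec"
  spec
}

#' Generate a branching astrocyte phantom
#'
#' @param spec an \code{\link{astroPhantomSpec}}.
#' @return list with \code{image} (\linkS4class{Micrograph}) and
#'   \code{truth}: exact per-phantom totals \code{branches},
#'   \code{junctions}, \code{endpoints}, \code{triplePoints},
#'   \code{quadruplePoints}, \code{totalLength} (um of stamped centreline,
#'   trees only), \code{nFragments}, \code{fragmentLengths} (um),
#'   \code{centerline} (logical matrix incl. fragments), and \code{mask}
#'   (dilated ideal binary mask).
#' @export
generateAstrocytes <- function(spec) {
  stopifnot(inherits(spec, "AstroPhantomSpec"))
  n <- spec$imageSize
  widPx <- max(1L, round(spec$processWidth / spec$pixelSize))
  armMaxPx <- max(spec$branchLength) / spec$pixelSize *
    (1 + (spec$branchingDepth == 2) * spec$childLengthFrac)
  withr::with_seed(streamSeed(spec$seed, 303L), {
    somata <- placePoints(spec$nSomata, n, n,
                          minDistPx = 2 * armMaxPx + 4 * widPx + 4,
                          marginPx = armMaxPx + widPx + 2,
                          allowTouching = FALSE)
    centerline <- matrix(FALSE, n, n)
    branches <- 0L; junctions <- 0L; endpoints <- 0L
    triple <- 0L; quadruple <- 0L; totalLen <- 0
    for (s in seq_len(spec$nSomata)) {
      tree <- stampTree(spec, somata[s, ])
      centerline[tree$idx] <- TRUE
      branches <- branches + tree$branches
      junctions <- junctions + tree$junctions
      endpoints <- endpoints + tree$endpoints
      triple <- triple + tree$triple
      quadruple <- quadruple + tree$quadruple
      totalLen <- totalLen + tree$length
    }
    treeline <- centerline
    fragLens <- numeric(0)
    if (spec$nFragments > 0) {
      clearance <- armMaxPx + 4 * widPx + 8
      placed <- 0L; tries <- 0L
      while (placed < spec$nFragments) {
        tries <- tries + 1L
        if (tries > 20000L)
          stop("could not place fragments clear of trees: overcrowded spec")
        cand <- c(runif(1, widPx + 6, n - widPx - 6),
                  runif(1, widPx + 6, n - widPx - 6))
        if (nrow(somata) > 0) {
          d2 <- (somata[, 1] - cand[1])^2 + (somata[, 2] - cand[2])^2
          if (min(d2) < clearance^2) next
        }
        lenUm <- runif(1, spec$fragmentLength[1], spec$fragmentLength[2])
        lenPx <- max(2, round(lenUm / spec$pixelSize))
        ang <- sample(0:3, 1) * pi / 4
        p1 <- cand + lenPx * c(-sin(ang), cos(ang))
        rc <- bresenham(cand[1], cand[2], p1[1], p1[2])
        if (any(rc < widPx + 3) || any(rc > n - widPx - 2)) next
        # keep fragments clear of everything already stamped
        box <- centerline[
          max(1, min(rc[, 1]) - 3 * widPx):min(n, max(rc[, 1]) + 3 * widPx),
          max(1, min(rc[, 2]) - 3 * widPx):min(n, max(rc[, 2]) + 3 * widPx)]
        if (any(box)) next
        centerline[rc] <- TRUE
        fragLens <- c(fragLens, pathLengthPx(rc) * spec$pixelSize)
        placed <- placed + 1L
      }
    }
    mask <- dilateMask(centerline, widPx)
    img <- matrix(spec$backgroundIntensity, n, n)
    img[mask] <- spec$intensity
    if (spec$noiseSd > 0)
      img <- img + rnorm(length(img), 0, spec$noiseSd)
    list(image = Micrograph(quantize8(img), spec$pixelSize),
         truth = list(branches = branches, junctions = junctions,
                      endpoints = endpoints, triplePoints = triple,
                      quadruplePoints = quadruple, totalLength = totalLen,
                      nFragments = spec$nFragments,
                      fragmentLengths = fragLens,
                      centerline = centerline, treeline = treeline,
                      mask = mask))
  })
}

# Stamp one tree; returns stamped indices and its exact topology counts.
stampTree <- function(spec, soma) {
  m <- spec$branchesPerSoma
  # distinct compass directions, multiples of 45 deg, spread apart
  dirs <- (seq_len(m) - 1L) * (8L %/% m) * pi / 4
  idx <- matrix(integer(0), 0, 2)
  totalLen <- 0
  branches <- 0L; endpoints <- 0L; junctions <- 1L
  for (ang in dirs) {
    lenPx <- runif(1, spec$branchLength[1], spec$branchLength[2]) /
      spec$pixelSize
    tip <- soma + lenPx * c(-sin(ang), cos(ang))
    rc <- bresenham(soma[1], soma[2], tip[1], tip[2])
    idx <- rbind(idx, rc)
    totalLen <- totalLen + pathLengthPx(rc)
    branches <- branches + 1L
    if (spec$branchingDepth == 2) {
      junctions <- junctions + 1L  # bifurcation at the tip
      for (dang in c(-pi / 4, pi / 4)) {
        ca <- ang + dang
        clen <- lenPx * spec$childLengthFrac
        ctip <- tip + clen * c(-sin(ca), cos(ca))
        crc <- bresenham(tip[1], tip[2], ctip[1], ctip[2])
        idx <- rbind(idx, crc)
        totalLen <- totalLen + pathLengthPx(crc)
        branches <- branches + 1L
        endpoints <- endpoints + 1L
      }
    } else {
      endpoints <- endpoints + 1L
    }
  }
  triple <- as.integer(m == 3) + if (spec$branchingDepth == 2) m else 0L
  quadruple <- as.integer(m == 4)
  list(idx = idx, branches = branches, junctions = junctions,
       endpoints = endpoints, triple = triple, quadruple = quadruple,
       length = totalLen * spec$pixelSize)
}

# Dilate a logical mask to the requested full width (disc brush).
dilateMask <- function(mask, widthPx) {
  if (widthPx <= 1L) return(mask)
  brushSize <- widthPx + (1L - widthPx %% 2L)  # odd
  if (brushSize < 3L) brushSize <- 3L
  k <- EBImage::makeBrush(brushSize, shape = "disc")
  EBImage::dilate(mask * 1, k) > 0
}
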