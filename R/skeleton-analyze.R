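# Topology-preserving 2D thinning and skeleton morphometry in the style of
# the AnalyzeSkeleton family: thin to a unit-width 8-connected skeleton,
# classify voxels by neighbour count, merge adjacent junction voxels into
# junctions, trace branches as slab paths, measure geometric branch lengths
# in um, and filter out sub-cutoff fragments before totalling.

#' Thin a binary image to a one-pixel-wide skeleton
#'
#' Guo-Hall two-subiteration thinning: preserves connectivity and produces
#' 8-connected unit-width skeletons. Iterates until no pixel changes.
#'
#' @param bin logical (or 0/1) matrix.
#' @return logical matrix, the skeleton.
#' @export
thinSkeleton <- function(bin) {
  if (!all(bin %in% c(0, 1, FALSE, TRUE))) stop("input must be binary")
  m <- (bin > 0) * 1L
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      p2 <- shiftMatrix(m,  1,  0)  # N  (row - 1 neighbour of each pixel)
      p3 <- shiftMatrix(m,  1, -1)  # NE
      p4 <- shiftMatrix(m,  0, -1)  # E
      p5 <- shiftMatrix(m, -1, -1)  # SE
      p6 <- shiftMatrix(m, -1,  0)  # S
      p7 <- shiftMatrix(m, -1,  1)  # SW
      p8 <- shiftMatrix(m,  0,  1)  # W
      p9 <- shiftMatrix(m,  1,  1)  # NW
      C  <- ((1L - p2) & (p3 | p4)) + ((1L - p4) & (p5 | p6)) +
            ((1L - p6) & (p7 | p8)) + ((1L - p8) & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      Nm <- pmin(N1, N2)
      m3 <- if (iter == 0) ((p6 | p7 | (1L - p9)) & p8)
            else           ((p2 | p3 | (1L - p5)) & p4)
      del <- (m == 1L) & (C == 1L) & (Nm >= 2L) & (Nm <= 3L) & (m3 == 0L)
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m > 0
}

# Count of 8-neighbours on the skeleton, per skeleton pixel.
neighborCount <- function(skel) {
  s <- skel * 1L
  acc <- matrix(0L, nrow(s), ncol(s))
  for (i in seq_len(nrow(MOORE)))
    acc <- acc + shiftMatrix(s, MOORE[i, 1], MOORE[i, 2])
  acc
}

# Label 8-connected components of a logical matrix via breadth-first
# search over the sparse foreground (skeletons are sparse).
label8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- integer(256L)
    queue[1L] <- start
    qhead <- 1L; qtail <- 1L
    lab[start] <- cur
    while (qhead <= qtail) {
      v <- queue[qhead]; qhead <- qhead + 1L
      r <- (v - 1L) %% nr + 1L
      cl <- (v - 1L) %/% nr + 1L
      for (i in seq_len(8L)) {
        rr <- r + MOORE[i, 1]; cc <- cl + MOORE[i, 2]
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        w <- (cc - 1L) * nr + rr
        if (mask[w] && lab[w] == 0L) {
          lab[w] <- cur
          qtail <- qtail + 1L
          if (qtail > length(queue)) queue <- c(queue, integer(length(queue)))
          queue[qtail] <- w
        }
      }
    }
  }
  lab
}

# Neighbours of linear index v on the skeleton, as linear indices.
skelNeighbors <- function(v, skel, nr, nc) {
  r <- (v - 1L) %% nr + 1L
  cl <- (v - 1L) %/% nr + 1L
  out <- integer(0)
  for (i in seq_len(8L)) {
    rr <- r + MOORE[i, 1]; cc <- cl + MOORE[i, 2]
    if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
    w <- (cc - 1L) * nr + rr
    if (skel[w]) out <- c(out, w)
  }
  out
}

stepLen <- function(v, w, nr) {
  r1 <- (v - 1L) %% nr; c1 <- (v - 1L) %/% nr
  r2 <- (w - 1L) %% nr; c2 <- (w - 1L) %/% nr
  sqrt((r1 - r2)^2 + (c1 - c2)^2)
}

#' Skeletonize a binary image and extract branch/junction morphometry
#'
#' Thins the input to a unit-width skeleton, classifies skeleton voxels by
#' 8-neighbour count (endpoint < 2, slab = 2, junction > 2), merges
#' adjacent junction voxels into single junctions, traces branches as slab
#' paths between endpoint/junction nodes with geometric lengths (steps of
#' 1 or sqrt(2) pixels, scaled by \code{pixelSize}), removes sub-cutoff
#' fragment components (no junction voxels and total length below
#' \code{cutoff}), and totals the metrics over the surviving skeleton.
#'
#' @param bin logical (or 0/1) matrix, the preprocessed binary image; may
#'   also be a \linkS4class{Micrograph} holding a binary image.
#' @param pixelSize um per pixel (taken from the Micrograph if given one).
#' @param cutoff um, fragment filter cutoff (default 0.7); set to 0 to
#'   disable.
#' @param thin logical; set FALSE if \code{bin} is already a unit-width
#'   skeleton.
#' @return list with \code{graph} (a \linkS4class{SkeletonGraph}) and
#'   \code{metrics} (list of class \code{SkeletonMetrics}: branches,
#'   branchLength, slabVoxels, junctionVoxels, junctions, endpointVoxels,
#'   triplePoints, quadruplePoints, averageLength).
#' @export
skeletonizeAndAnalyze <- function(bin, pixelSize = NULL, cutoff = 0.7,
                                  thin = TRUE) {
  if (is(bin, "Micrograph")) {
    if (is.null(pixelSize)) pixelSize <- pixelSize(bin)
    bin <- pixels(bin) > 127
  }
  if (is.null(pixelSize) || pixelSize <= 0)
    stop("pixelSize (um) must be supplied and positive")
  if (!all(bin %in% c(0, 1, FALSE, TRUE))) stop("input must be binary")
  skel <- if (thin) thinSkeleton(bin) else (bin > 0)
  graph <- traceSkeleton(skel, pixelSize)
  graph <- pruneFragments(graph, cutoff)
  list(graph = graph, metrics = skeletonMetrics(graph))
}

# Build the classified SkeletonGraph with traced branches.
traceSkeleton <- function(skel, pixelSize) {
  nr <- nrow(skel); nc <- ncol(skel)
  nb <- neighborCount(skel)
  voxelClass <- matrix(0L, nr, nc)
  voxelClass[skel & nb < 2] <- 1L   # endpoint
  voxelClass[skel & nb == 2] <- 2L  # slab
  voxelClass[skel & nb > 2] <- 3L   # junction
  comp <- label8(skel)
  juncMask <- voxelClass == 3L
  juncLab <- label8(juncMask)
  nJunc <- max(juncLab)
  # junction-cluster centroids; branch attachments are measured to the
  # centroid so cluster-internal steps are not lost from branch lengths
  jCentroid <- if (nJunc > 0) {
    ji <- which(juncLab > 0)
    jr <- (ji - 1L) %% nr + 1L
    jcl <- (ji - 1L) %/% nr + 1L
    cbind(tapply(jr, juncLab[ji], mean), tapply(jcl, juncLab[ji], mean))
  } else matrix(numeric(0), 0, 2)
  distToJunction <- function(v, j) {
    r <- (v - 1L) %% nr + 1L
    cl <- (v - 1L) %/% nr + 1L
    sqrt((r - jCentroid[j, 1])^2 + (cl - jCentroid[j, 2])^2)
  }
  visited <- matrix(FALSE, nr, nc)

  branchRows <- list()
  addBranch <- function(lenPx, compId, j1, j2, nVox) {
    branchRows[[length(branchRows) + 1L]] <<- data.frame(
      component = compId, length_um = lenPx * pixelSize,
      junction1 = j1, junction2 = j2, nVoxels = nVox)
  }

  # Walk from `start` (a slab or endpoint voxel) away from junction cluster
  # jFrom (0 if none). Slab continuation takes priority over junction
  # termination so paths are not cut short by diagonal junction contacts.
  walk <- function(start, jFrom) {
    visited[start] <<- TRUE
    lenPx <- 0
    cur <- start
    nVox <- 1L
    jTo <- 0L
    repeat {
      nbrs <- skelNeighbors(cur, skel, nr, nc)
      cand <- nbrs[juncLab[nbrs] == 0L & !visited[nbrs]]
      if (length(cand)) {
        nxt <- cand[1]
        lenPx <- lenPx + stepLen(cur, nxt, nr)
        visited[nxt] <<- TRUE
        cur <- nxt
        nVox <- nVox + 1L
        next
      }
      jn <- nbrs[juncLab[nbrs] > 0L]
      if (cur == start && jFrom > 0L)
        jn <- jn[juncLab[jn] != jFrom]  # entry cluster handled by caller
      if (length(jn)) {
        jTo <- juncLab[jn[1]]
        lenPx <- lenPx + distToJunction(cur, jTo)
      }
      break
    }
    list(lenPx = lenPx, jTo = jTo, nVox = nVox, end = cur)
  }

  # branch starts: slab/endpoint voxels adjacent to a junction cluster
  allIdx <- which(skel)
  starts <- allIdx[voxelClass[allIdx] %in% c(1L, 2L)]
  adjJunc <- integer(length(starts))
  for (i in seq_along(starts)) {
    nbrs <- skelNeighbors(starts[i], skel, nr, nc)
    j <- juncLab[nbrs]
    adjJunc[i] <- if (any(j > 0L)) j[j > 0L][1] else 0L
  }
  # 1) branches emanating from junctions
  for (i in seq_along(starts)) {
    s <- starts[i]
    if (adjJunc[i] == 0L || visited[s]) next
    w <- walk(s, adjJunc[i])
    # entry step from the junction-cluster centroid to the start voxel
    entry <- distToJunction(s, adjJunc[i])
    addBranch(w$lenPx + entry, comp[s], adjJunc[i], w$jTo, w$nVox)
  }
  # 2) junction-free paths (isolated lines, dots): start at endpoints
  for (s in allIdx[voxelClass[allIdx] == 1L]) {
    if (visited[s]) next
    w <- walk(s, 0L)
    addBranch(w$lenPx, comp[s], 0L, w$jTo, w$nVox)
  }
  # 3) leftover pure cycles (rings of slab voxels)
  for (s in allIdx[voxelClass[allIdx] == 2L]) {
    if (visited[s]) next
    w <- walk(s, 0L)
    # close the ring if the walk returned next to the start
    closing <- if (w$end != s && w$end %in% skelNeighbors(s, skel, nr, nc))
      stepLen(w$end, s, nr) else 0
    addBranch(w$lenPx + closing, comp[s], 0L, 0L, w$nVox)
  }
  branches <- if (length(branchRows)) do.call(rbind, branchRows) else
    data.frame(component = integer(0), length_um = numeric(0),
               junction1 = integer(0), junction2 = integer(0),
               nVoxels = integer(0))
  # per-junction emanating branch count
  if (nJunc > 0) {
    cnt <- tabulate(c(branches$junction1, branches$junction2), nJunc)
    jcomp <- vapply(seq_len(nJunc), function(j) {
      comp[which(juncLab == j)[1]]
    }, integer(1))
    junctions <- data.frame(id = seq_len(nJunc), component = jcomp,
                            nBranches = cnt)
  } else {
    junctions <- data.frame(id = integer(0), component = integer(0),
                            nBranches = integer(0))
  }
  new("SkeletonGraph", skeleton = skel, voxelClass = voxelClass,
      branches = branches, junctions = junctions, components = comp,
      pixelSize = pixelSize)
}

#' Remove sub-cutoff skeleton fragments
#'
#' Deletes connected skeleton components that contain no junction voxels
#' (short free-lying residues, including degenerate single-voxel dots) and
#' whose total traced length is below \code{cutoff} um. Idempotent; every
#' count metric can only decrease.
#'
#' @param graph a \linkS4class{SkeletonGraph}.
#' @param cutoff um; 0 disables.
#' @return the filtered \linkS4class{SkeletonGraph}.
#' @export
pruneFragments <- function(graph, cutoff = 0.7) {
  stopifnot(is(graph, "SkeletonGraph"))
  if (cutoff <= 0 || nrow(graph@branches) == 0L) return(graph)
  compLen <- tapply(graph@branches$length_um, graph@branches$component, sum)
  hasJunc <- unique(graph@junctions$component)
  drop <- as.integer(names(compLen))[compLen < cutoff &
            !(as.integer(names(compLen)) %in% hasJunc)]
  if (!length(drop)) return(graph)
  keepMask <- !(graph@components %in% drop)
  skel <- graph@skeleton & keepMask
  vc <- graph@voxelClass
  vc[!keepMask] <- 0L
  comp <- graph@components
  comp[!keepMask] <- 0L
  branches <- graph@branches[!(graph@branches$component %in% drop), ,
                             drop = FALSE]
  junctions <- graph@junctions[!(graph@junctions$component %in% drop), ,
                               drop = FALSE]
  new("SkeletonGraph", skeleton = skel, voxelClass = vc,
      branches = branches, junctions = junctions, components = comp,
      pixelSize = graph@pixelSize)
}

#' Total skeleton metrics of a SkeletonGraph
#'
#' @param graph a \linkS4class{SkeletonGraph}.
#' @return list of class \code{SkeletonMetrics}: \code{branches} (count),
#'   \code{branchLength} (um, total), \code{slabVoxels},
#'   \code{junctionVoxels}, \code{junctions}, \code{endpointVoxels},
#'   \code{triplePoints}, \code{quadruplePoints}, and \code{averageLength}
#'   (um; \code{NA} when there are no branches).
#' @export
skeletonMetrics <- function(graph) {
  stopifnot(is(graph, "SkeletonGraph"))
  vc <- graph@voxelClass
  nBranches <- nrow(graph@branches)
  totLen <- sum(graph@branches$length_um)
  out <- list(
    branches = nBranches,
    branchLength = totLen,
    slabVoxels = sum(vc == 2L),
    junctionVoxels = sum(vc == 3L),
    junctions = nrow(graph@junctions),
    endpointVoxels = sum(vc == 1L),
    triplePoints = sum(graph@junctions$nBranches == 3L),
    quadruplePoints = sum(graph@junctions$nBranches == 4L),
    averageLength = if (nBranches > 0) totLen / nBranches else NA_real_)
  class(out) <- "SkeletonMetrics"
  out
}

#' @export
print.SkeletonMetrics <- function(x, ...) {
  cat(sprintf(
    "SkeletonMetrics: %d branches, %.2f um total (avg %.2f um)\n",
    x$branches, x$branchLength,
    ifelse(is.na(x$averageLength), NaN, x$averageLength)))
  cat(sprintf("  junctions %d (triple %d, quadruple %d), endpoints %d\n",
              x$junctions, x$triplePoints, x$quadruplePoints,
              x$endpointVoxels))
  invisible(x)
}
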