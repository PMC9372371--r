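test_that("hand-built skeletons yield the expected metrics", {
  # horizontal 21-px line at 0.114 um/px: one branch of 20 steps
  m <- matrix(FALSE, 30, 40); m[15, 10:30] <- TRUE
  r <- skeletonizeAndAnalyze(m, pixelSize = 0.114, cutoff = 0,
                             thin = FALSE)
  expect_equal(r$metrics$branches, 1)
  expect_equal(r$metrics$branchLength, 20 * 0.114)
  expect_equal(r$metrics$endpointVoxels, 2)
  expect_equal(r$metrics$junctions, 0)
  expect_equal(r$metrics$averageLength, r$metrics$branchLength)
  # T shape: three arms from one point
  t3 <- matrix(FALSE, 40, 40)
  t3[20, 20:32] <- TRUE; t3[8:20, 20] <- TRUE; t3[20, 8:20] <- TRUE
  rt <- skeletonizeAndAnalyze(t3, pixelSize = 0.114, cutoff = 0,
                              thin = FALSE)
  expect_equal(rt$metrics$branches, 3)
  expect_equal(rt$metrics$junctions, 1)
  expect_equal(rt$metrics$endpointVoxels, 3)
  expect_equal(rt$metrics$triplePoints, 1)
  expect_equal(rt$metrics$quadruplePoints, 0)
  # X shape: quadruple point
  x4 <- matrix(FALSE, 40, 40)
  x4[20, 8:32] <- TRUE; x4[8:32, 20] <- TRUE
  rx <- skeletonizeAndAnalyze(x4, pixelSize = 0.114, cutoff = 0,
                              thin = FALSE)
  expect_equal(rx$metrics$branches, 4)
  expect_equal(rx$metrics$quadruplePoints, 1)
  expect_error(skeletonizeAndAnalyze(matrix(2, 4, 4), pixelSize = 1),
               "binary")
  expect_error(skeletonizeAndAnalyze(matrix(TRUE, 4, 4), pixelSize = -1),
               "pixelSize")
})

test_that("the 0.7 um fragment filter removes exactly the sub-cutoff
           residues", {
  # isolated 4-px segment (0.342 um) next to a large T tree
  m <- matrix(FALSE, 60, 60)
  m[30, 20:40] <- TRUE; m[15:30, 30] <- TRUE; m[30:45, 30] <- TRUE
  big <- skeletonizeAndAnalyze(m, pixelSize = 0.114, cutoff = 0.7,
                               thin = FALSE)
  m2 <- m; m2[50, 10:13] <- TRUE
  both <- skeletonizeAndAnalyze(m2, pixelSize = 0.114, cutoff = 0.7,
                                thin = FALSE)
  expect_equal(both$metrics, big$metrics)
  # without the filter the fragment is counted
  raw <- skeletonizeAndAnalyze(m2, pixelSize = 0.114, cutoff = 0,
                               thin = FALSE)
  expect_equal(raw$metrics$branches, big$metrics$branches + 1)
  # a fragment longer than the cutoff survives
  m3 <- m; m3[50, 10:20] <- TRUE  # 10 steps = 1.14 um
  kept <- skeletonizeAndAnalyze(m3, pixelSize = 0.114, cutoff = 0.7,
                                thin = FALSE)
  expect_equal(kept$metrics$branches, big$metrics$branches + 1)
})

test_that("fragment filtering is idempotent and only decreases counts", {
  withr::with_seed(31, {
    for (s in 1:5) {
      ph <- generateAstrocytes(astroPhantomSpec(nSomata = 2,
                                                nFragments = 3,
                                                imageSize = 400,
                                                seed = s))
      r0 <- skeletonizeAndAnalyze(ph$truth$mask, pixelSize = 0.114,
                                  cutoff = 0)
      g1 <- pruneFragments(r0$graph, 0.7)
      g2 <- pruneFragments(g1, 0.7)
      m0 <- skeletonMetrics(r0$graph)
      m1 <- skeletonMetrics(g1)
      m2 <- skeletonMetrics(g2)
      expect_identical(m1, m2)  # idempotent
      for (nm in c("branches", "branchLength", "slabVoxels",
                   "junctionVoxels", "junctions", "endpointVoxels",
                   "triplePoints", "quadruplePoints"))
        expect_lte(m1[[nm]], m0[[nm]])
    }
  })
})

test_that("voxel classes partition every skeleton and average length is
           consistent", {
  for (s in 1:6) {
    ph <- generateAstrocytes(astroPhantomSpec(
      nSomata = 2, branchesPerSoma = 3 + s %% 2,
      branchingDepth = 1 + s %% 2, seed = s))
    r <- skeletonizeAndAnalyze(ph$truth$mask, pixelSize = 0.114)
    vc <- r$graph@voxelClass
    expect_equal(sum(vc > 0), sum(r$graph@skeleton))
    m <- r$metrics
    expect_equal(m$endpointVoxels + m$junctionVoxels + m$slabVoxels,
                 sum(r$graph@skeleton))
    expect_equal(m$averageLength, m$branchLength / m$branches)
    expect_lte(m$triplePoints + m$quadruplePoints, m$junctions)
  }
})

test_that("thinning recovers planted topology exactly on noiseless
           phantoms", {
  ok <- 0; lenErr <- numeric(0)
  for (s in 1:10) {
    ph <- generateAstrocytes(astroPhantomSpec(
      nSomata = 3, branchesPerSoma = 3 + s %% 2,
      branchingDepth = 1 + (s %% 3 == 0), seed = 100 + s))
    r <- skeletonizeAndAnalyze(ph$truth$mask, pixelSize = 0.114)
    ok <- ok + topologyMatches(r$metrics, ph$truth)
    lenErr <- c(lenErr, abs(r$metrics$branchLength -
                            ph$truth$totalLength) / ph$truth$totalLength)
  }
  expect_equal(ok, 10)
  expect_lt(max(lenErr), 0.05)
})

test_that("the preprocessing cascade behaves on degenerate and ideal
           inputs", {
  cfg <- skeletonConfig()
  # blank image -> empty binary
  blank <- preprocessGfap(Micrograph(matrix(210, 150, 150), 0.114), cfg)
  expect_equal(sum(blank), 0)
  # salt-and-pepper speckle: no isolated foreground pixels survive
  withr::with_seed(7, {
    img <- matrix(210, 200, 200)
    img[sample(length(img), 150)] <- 40
    sp <- preprocessGfap(Micrograph(img, 0.114), cfg)
    nb <- dtihisto:::neighborCount(sp)
    expect_equal(sum(sp & nb == 0), 0)
  })
  # ideal phantom: binary equals the dilated truth mask up to boundary
  # pixels
  ph <- generateAstrocytes(astroPhantomSpec(nSomata = 3, seed = 2))
  bin <- preprocessGfap(ph$image, cfg)
  agr <- maskAgreement(bin, ph$truth$mask)
  expect_gte(agr["precision"], 0.95)
  expect_gte(agr["recall"], 0.95)
  # full cascade preserves topology on a noisy phantom
  ph2 <- generateAstrocytes(astroPhantomSpec(nSomata = 3, noiseSd = 8,
                                             seed = 4))
  r2 <- skeletonizeAndAnalyze(preprocessGfap(ph2$image, cfg),
                              pixelSize = 0.114)
  expect_true(topologyMatches(r2$metrics, ph2$truth))
  # region-specific thresholds resolve; unknown region errors
  expect_equal(skeletonConfig(region = "cc")$thresholdUpper, 218)
  expect_equal(skeletonConfig(region = "layerVI")$thresholdUpper, 219)
  expect_error(skeletonConfig(region = "CA1"), "unknown region")
})

test_that("thinning preserves connectivity and reduces to unit width", {
  withr::with_seed(12, {
    ph <- generateAstrocytes(astroPhantomSpec(nSomata = 3, seed = 55))
    mask <- ph$truth$mask
    sk <- thinSkeleton(mask)
    expect_true(all(mask[sk]))  # skeleton is a subset of the mask
    # same number of connected components before and after
    nComp <- function(m) max(dtihisto:::label8(m))
    expect_equal(nComp(sk), nComp(mask))
    # unit width: no 2x2 block fully on the skeleton
    s <- sk * 1L
    blocks <- s[-1, -1] + s[-nrow(s), -1] + s[-1, -ncol(s)] +
      s[-nrow(s), -ncol(s)]
    expect_lt(max(blocks), 4L)
    expect_error(thinSkeleton(matrix(2, 3, 3)), "binary")
  })
})
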