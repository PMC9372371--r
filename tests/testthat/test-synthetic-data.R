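test_that("Nissl phantom honours count, spacing, and seed contract", {
  # empty case
  blank <- generateNissl(nisslPhantomSpec(nCells = 0, imageSize = 64))
  expect_equal(blank$truth$count, 0)
  expect_equal(length(unique(as.numeric(pixels(blank$image)))), 1L)
  # 50 non-overlapping disks: component count of the ideal mask is the
  # independent oracle for the recorded ground truth
  ph <- generateNissl(nisslPhantomSpec(nCells = 50, noiseSd = 0, seed = 3))
  expect_equal(ph$truth$count, 50)
  comps <- max(EBImage::bwlabel(EBImage::Image(ph$truth$mask * 1)))
  expect_equal(comps, 50)
  # non-overlap: pairwise centre distances exceed the radii sums
  ctr <- ph$truth$centers
  dmat <- as.matrix(dist(ctr[, c("row", "col")]))
  diag(dmat) <- Inf
  expect_true(min(dmat) >= 2 * max(ctr$radius_um))
  # seed contract: different layouts, same count; same seed bit-identical
  ph2 <- generateNissl(nisslPhantomSpec(nCells = 50, noiseSd = 0, seed = 4))
  expect_equal(ph2$truth$count, 50)
  expect_false(identical(ph$truth$centers, ph2$truth$centers))
  ph3 <- generateNissl(nisslPhantomSpec(nCells = 50, noiseSd = 0, seed = 3))
  expect_identical(pixels(ph$image), pixels(ph3$image))
  # overcrowded spec errors out
  expect_error(
    generateNissl(nisslPhantomSpec(nCells = 400, imageSize = 64)),
    "overcrowded")
})

test_that("fiber phantom orientation statistics follow the dispersion", {
  # kappa above the cap: all segments parallel
  par <- generateFibers(fiberPhantomSpec(nFibers = 30,
                                         dispersionKappa = 1e6))
  expect_equal(length(unique(par$truth$orientations)), 1L)
  expect_equal(par$truth$circularVariance, 0)
  # kappa = 0: uniform orientations, circular variance near 1
  unif <- generateFibers(fiberPhantomSpec(nFibers = 400,
                                          dispersionKappa = 0, seed = 5))
  expect_gt(unif$truth$circularVariance, 0.85)
  # no fibers: flat background
  none <- generateFibers(fiberPhantomSpec(nFibers = 0, noiseSd = 0))
  expect_equal(length(unique(as.numeric(pixels(none$image)))), 1L)
  # reproducibility
  a <- generateFibers(fiberPhantomSpec(seed = 11))
  b <- generateFibers(fiberPhantomSpec(seed = 11))
  expect_identical(pixels(a$image), pixels(b$image))
})

test_that("astrocyte phantom records exact topology by construction", {
  # one soma, 3 straight arms: 3 branches, 1 junction, 3 endpoints,
  # 1 triple point
  y3 <- generateAstrocytes(astroPhantomSpec(nSomata = 1,
                                            branchesPerSoma = 3, seed = 2))
  expect_equal(y3$truth$branches, 3)
  expect_equal(y3$truth$junctions, 1)
  expect_equal(y3$truth$endpoints, 3)
  expect_equal(y3$truth$triplePoints, 1)
  expect_equal(y3$truth$quadruplePoints, 0)
  # one soma, 4 arms: one quadruple point
  x4 <- generateAstrocytes(astroPhantomSpec(nSomata = 1,
                                            branchesPerSoma = 4, seed = 2))
  expect_equal(x4$truth$quadruplePoints, 1)
  expect_equal(x4$truth$triplePoints, 0)
  # additivity over disjoint trees: two Y trees double the single-Y counts
  y2 <- generateAstrocytes(astroPhantomSpec(nSomata = 2,
                                            branchesPerSoma = 3, seed = 2))
  expect_equal(y2$truth$branches, 2 * y3$truth$branches)
  expect_equal(y2$truth$junctions, 2 * y3$truth$junctions)
  expect_equal(y2$truth$endpoints, 2 * y3$truth$endpoints)
  # bifurcating trees: per-tree 9 branches, 4 junctions, 6 endpoints,
  # 4 triple points
  d2 <- generateAstrocytes(astroPhantomSpec(nSomata = 1,
                                            branchesPerSoma = 3,
                                            branchingDepth = 2, seed = 6))
  expect_equal(d2$truth$branches, 9)
  expect_equal(d2$truth$junctions, 4)
  expect_equal(d2$truth$endpoints, 6)
  expect_equal(d2$truth$triplePoints, 4)
  # planted fragments are below the cutoff and recorded
  fr <- generateAstrocytes(astroPhantomSpec(nSomata = 2, nFragments = 3,
                                            imageSize = 400, seed = 8))
  expect_equal(fr$truth$nFragments, 3)
  expect_true(all(fr$truth$fragmentLengths < 0.7))
})

test_that("cohort generator implements the linear model exactly at zero
           noise and at the stated design size", {
  ct <- generateCohort(cohortSpec(noiseSd = 0, seed = 5))
  d <- cohortData(ct)
  expect_equal(nrow(d), 68)  # 17 animals x 4 regions
  expect_equal(length(unique(d$animal_id)), 17)
  tr <- cohortTruth(ct)
  yhat <- as.matrix(d[, c("FA", "RD", "MD", "CP", "CS")]) %*%
    tr$b[1, ] + tr$c[1]
  expect_equal(d$y, as.numeric(yhat), tolerance = 1e-12)
  # eigenvalues are sorted and positive everywhere
  expect_true(all(d$lambda1 >= d$lambda2 & d$lambda2 >= d$lambda3 &
                  d$lambda3 > 0))
  # reproducible
  ct2 <- generateCohort(cohortSpec(noiseSd = 0, seed = 5))
  expect_identical(cohortData(ct2), d)
})

test_that("null cohorts (b = 0) show no predictor-response correlation", {
  rs <- vapply(1:20, function(s) {
    ct <- generateCohort(cohortSpec(
      K = 60, b = c(FA = 0, RD = 0, MD = 0, CP = 0, CS = 0),
      noiseSd = 0.2, seed = s))
    d <- cohortData(ct)
    max(abs(cor(d$y, d[, c("FA", "RD", "MD", "CP", "CS")])))
  }, numeric(1))
  # n = 240 rows: null |R| beyond 0.25 would be a > 3.9 sigma event
  expect_true(mean(rs < 0.25) >= 0.9)
})

test_that("eigenvalue draws converge to the specified marginals", {
  # corpus callosum has well-separated eigenvalues, so the sort step
  # almost never reorders draws there
  ct <- generateCohort(cohortSpec(K = 120,
                                  groupLabels = rep("control", 120),
                                  seed = 17))
  d <- cohortData(ct)
  cc <- d[d$region == "cc", ]
  pr <- defaultEigenvalueParams()
  pr <- pr[pr$group == "control" & pr$region == "cc", ]
  n <- nrow(cc)
  expect_lt(abs(mean(cc$lambda1) - pr$m1), 3 * pr$s1 / sqrt(n) + 1e-3)
  expect_lt(abs(mean(cc$lambda3) - pr$m3), 3 * pr$s3 / sqrt(n) + 1e-3)
  expect_lt(abs(sd(cc$lambda1) - pr$s1), 0.25 * pr$s1)
})
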