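# Helper: cohort-like data.frame with arbitrary predictor content.
makeModelFrame <- function(n, f) {
  d <- data.frame(animal_id = sprintf("A%02d", rep(seq_len(n %/% 4), 4)),
                  group = "SE",
                  region = rep(c("cc", "layerV", "layerVI", "CA3b"),
                               each = n %/% 4))
  d <- d[seq_len(n), ]
  cbind(d, f(n))
}

test_that("closed-form adjusted R2 and F agree with lm and with the
           printed worked examples", {
  # closed forms against lm's own summary on a random fit
  withr::with_seed(2, {
    ct <- generateCohort(cohortSpec(targetR2 = 0.7, seed = 2))
    fit <- fitMultivariate(ct, "y", nBoot = 0)
    sm <- summary(fit$fit)
    expect_equal(fit$R2adj, sm$adj.r.squared, tolerance = 1e-12)
    expect_equal(fit$F, unname(sm$fstatistic["value"]),
                 tolerance = 1e-10)
  })
  # worked examples: published multivariate fits at n = 68, p = 5.
  # Inputs are printed to 3 decimals, and (1 - R2) rounding propagates by
  # the factor (n-1)/(n-p-1) = 1.08, so agreement is to one unit in the
  # last printed digit.
  expect_equal(adjustedR2(0.822, 68, 5), 0.807, tolerance = 1e-3)
  expect_equal(adjustedR2(0.855, 68, 5), 0.843, tolerance = 1e-3)
  expect_equal(adjustedR2(0.557, 68, 5), 0.521, tolerance = 2e-3)
  expect_equal(adjustedR2(0.507, 68, 5), 0.467, tolerance = 2e-3)
})

test_that("noiseless cohorts are interpolated exactly", {
  ct <- generateCohort(cohortSpec(noiseSd = 0, seed = 8))
  fit <- suppressWarnings(fitMultivariate(ct, "y", nBoot = 0))
  tr <- cohortTruth(ct)
  expect_equal(unname(fit$b), unname(tr$b[1, ]), tolerance = 1e-8)
  expect_equal(fit$c, tr$c[1], tolerance = 1e-8)
  expect_equal(fit$R2, 1, tolerance = 1e-12)
  cv <- suppressWarnings(loaoCv(ct, "y"))
  expect_equal(cv$Rcv, 1, tolerance = 1e-8)
  expect_equal(cv$Q2, 1, tolerance = 1e-8)
})

test_that("permuted responses behave like the null distribution", {
  withr::with_seed(4, {
    ct <- generateCohort(cohortSpec(targetR2 = 0.8, seed = 4))
    d <- cohortData(ct)
    r2s <- numeric(200); fp <- numeric(200)
    for (i in 1:200) {
      d$yp <- sample(d$y)
      f <- fitMultivariate(d, "yp", nBoot = 0)
      r2s[i] <- f$R2; fp[i] <- f$pF
    }
    # E[R2] under the null is p/(n-1) = 5/67
    expect_lt(abs(mean(r2s) - 5 / 67), 0.03)
    expect_gte(mean(fp > 0.05), 0.9)
  })
})

test_that("structural collinearity raises a named singularity error", {
  ct <- generateCohort(cohortSpec(seed = 6))
  expect_error(
    fitMultivariate(ct, "y",
                    predictors = c("FA", "AD", "RD", "MD", "CL",
                                   "CP", "CS")),
    "AD = 3\\*MD - 2\\*RD")
  expect_error(
    fitMultivariate(ct, "y",
                    predictors = c("FA", "RD", "MD", "CL", "CP", "CS")),
    "CL = 1 - CP - CS")
})

test_that("univariate Pearson analysis matches its closed relations", {
  d <- makeModelFrame(40, function(n) {
    x <- seq_len(n)
    data.frame(FA = x, y = 2 * x)
  })
  r <- pearsonUnivariate(d, "y", "FA")
  expect_equal(r$R, 1)
  expect_equal(r$R2, 1)
  # printed consistency: R = 0.858 implies R2 = 0.736
  expect_equal(round(0.858^2, 3), 0.736)
  expect_error(pearsonUnivariate(
    makeModelFrame(12, function(n) data.frame(FA = 1, y = rnorm(n))),
    "y", "FA"), "zero variance")
  # null sampling distribution at n = 68: P(|R| < 0.24) is 0.951 exactly
  # (t with 66 df), so assert above the 3-sigma binomial floor at 1000
  # draws
  withr::with_seed(9, {
    hits <- vapply(1:1000, function(i) {
      abs(cor(rnorm(68), rnorm(68))) < 0.24
    }, logical(1))
    expect_gte(mean(hits), 0.93)
  })
})

test_that("pearsonTable applies BH-FDR within its family", {
  ct <- generateCohort(cohortSpec(targetR2 = 0.6, seed = 12))
  tab <- pearsonTable(ct, "y")
  expect_equal(nrow(tab), 5)
  expect_true(all(tab$q >= tab$p))
  expect_equal(tab$R2, tab$R^2)
})

test_that("Q2 matches an independently coded evaluation of the printed
           formula on the same folds", {
  bruteQ2 <- function(y, yhat) {
    KJ <- length(y)
    num <- sum((y - yhat)^2) / KJ
    den <- sum((y - mean(y))^2) / KJ
    1 - num / den
  }
  ct <- generateCohort(cohortSpec(targetR2 = 0.7, seed = 14))
  cv <- loaoCv(ct, "y")
  expect_equal(cv$Q2, bruteQ2(cv$predictions$y, cv$predictions$yhat),
               tolerance = 1e-12)
  # frozen-mean predictions give Q2 = 0 by the formula
  y <- cv$predictions$y
  expect_equal(q2Score(y, rep(mean(y), length(y))), 0)
  # Q2 = 1 iff predictions equal truths
  expect_equal(q2Score(y, y), 1)
})

test_that("leave-one-animal-out pools every animal's held-out rows", {
  ct <- generateCohort(cohortSpec(targetR2 = 0.8, seed = 15))
  cv <- loaoCv(ct, "y")
  pr <- cv$predictions
  expect_equal(nrow(pr), 68)
  expect_equal(sort(unique(pr$animal_id)),
               sort(unique(cohortData(ct)$animal_id)))
  expect_true(abs(cv$Rcv) <= 1)
  expect_lte(cv$Q2, 1)
})

test_that("leave-one-region-out degrades where the relation differs and
           is symmetric for J = 2", {
  withr::with_seed(20, {
    # three regions share y = 2 FA; the fourth has disjoint FA range and
    # an inverted relation, mimicking an extrapolation failure
    d <- makeModelFrame(48, function(n) data.frame(FA = NA, RD = rnorm(n, 1, 0.1),
      MD = rnorm(n, 1, 0.1), CP = rnorm(n, 0.2, 0.05),
      CS = rnorm(n, 0.5, 0.05), y = NA))
    inA <- d$region != "CA3b"
    d$FA[inA] <- runif(sum(inA), 0.2, 0.5)
    d$FA[!inA] <- runif(sum(!inA), 0.7, 0.9)
    d$y[inA] <- 2 * d$FA[inA] + rnorm(sum(inA), 0, 0.02)
    d$y[!inA] <- -2 * d$FA[!inA] + 4 + rnorm(sum(!inA), 0, 0.02)
    lr <- loroCv(d, "y")
    rCA3b <- lr$perRegion$R[lr$perRegion$region == "CA3b"]
    rOthers <- lr$perRegion$R[lr$perRegion$region != "CA3b"]
    expect_true(all(rOthers > 0.8))
    expect_lt(rCA3b, min(rOthers) - 0.5)
  })
  # J = 2: the two folds are exact train/test swaps
  ct <- generateCohort(cohortSpec(J = 2, targetR2 = 0.9, seed = 21))
  lr2 <- loroCv(ct, "y")
  expect_equal(nrow(lr2$perRegion), 2)
  d2 <- cohortData(ct)
  fitA <- lm(y ~ FA + RD + MD + CP + CS,
             data = d2[d2$region == "cc", ])
  manual <- predict(fitA, newdata = d2[d2$region == "layerV", ])
  got <- lr2$predictions[lr2$predictions$region == "layerV", ]
  expect_equal(got$yhat, unname(manual), tolerance = 1e-10)
})

test_that("null cohorts give non-positive mean Q2 (honest CV)", {
  q2 <- vapply(1:40, function(s) {
    ct <- generateCohort(cohortSpec(
      b = c(FA = 0, RD = 0, MD = 0, CP = 0, CS = 0),
      noiseSd = 0.3, seed = s))
    loaoCv(ct, "y")$Q2
  }, numeric(1))
  expect_lte(mean(q2), 0)
})

test_that("OLS estimates of the generating coefficients are unbiased
           within Monte Carlo tolerance", {
  nSim <- 60
  bh <- matrix(NA_real_, nSim, 5)
  for (s in seq_len(nSim)) {
    ct <- generateCohort(cohortSpec(targetR2 = 0.8, seed = 300 + s))
    bh[s, ] <- fitMultivariate(ct, "y", nBoot = 0)$b
  }
  b <- cohortTruth(generateCohort(cohortSpec(seed = 1)))$b[1, ]
  se <- apply(bh, 2, sd) / sqrt(nSim)
  # unbiasedness: each mean within 4 standard errors of truth
  expect_true(all(abs(colMeans(bh) - b) < 4 * se))
})

test_that("model evaluation table collects fit and CV quantities", {
  ct <- generateCohort(cohortSpec(
    b = rbind(c(FA = 0.9, RD = -0.8, MD = 0.4, CP = 0.5, CS = -0.6),
              c(FA = 0, RD = 0, MD = 0, CP = 0, CS = 0)),
    noiseSd = c(0.05, 0.3), seed = 30))
  tab <- modelEvaluationTable(ct, c("y1", "y2"))
  expect_equal(nrow(tab), 2)
  expect_true(all(c("R2", "R2adj", "F", "Rcv", "Q2", "q") %in%
                  names(tab)))
  expect_gt(tab$R2[1], tab$R2[2])
  # animal-block bootstrap CI brackets the point estimate
  f <- fitMultivariate(ct, "y1", nBoot = 1000, seed = 3)
  expect_true(f$R2ci[1] <= f$R2 && f$R2 <= f$R2ci[2])
})
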