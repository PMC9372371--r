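# Cohort simulator: animal x region tables with a known linear relation
# between DTI predictors and histology responses. Predictors are computed
# from drawn eigenvalue triples, so they inherit the structural collinearity
# of real DTI scalars (all are functions of just three eigenvalues).

#' Default per-(group, region) eigenvalue distributions
#'
#' Means and SDs (units 1e-3 mm^2/s) for the three sorted tensor
#' eigenvalues in each of the four analysed regions, for control and
#' post-status-epilepticus (SE) animals. Values are chosen to be realistic
#' for rat brain at 7 T: the corpus callosum is strongly anisotropic,
#' cortical layers nearly isotropic, and the SE hippocampal CA3b shows the
#' characteristic anisotropy increase (FA up, CS down) that makes the
#' region distributions heterogeneous.
#'
#' @return data.frame with columns group, region, m1..m3, s1..s3.
#' @export
defaultEigenvalueParams <- function() {
  rbind(
    data.frame(group = "control",
               region = c("cc", "layerV", "layerVI", "CA3b"),
               m1 = c(1.55, 0.92, 0.94, 1.00),
               m2 = c(0.52, 0.74, 0.73, 0.80),
               m3 = c(0.36, 0.62, 0.60, 0.70)),
    data.frame(group = "SE",
               region = c("cc", "layerV", "layerVI", "CA3b"),
               m1 = c(1.45, 0.94, 1.00, 1.16),
               m2 = c(0.56, 0.75, 0.70, 0.76),
               m3 = c(0.42, 0.64, 0.55, 0.56))
  ) |> transform(s1 = 0.07, s2 = 0.045, s3 = 0.04)
}

#' Specification for a synthetic cohort table
#'
#' K animals by J regions; per row an eigenvalue triple is drawn from the
#' (group, region) distribution, the five DTI predictors (FA, RD, MD, CP,
#' CS) are computed from it, and each histology response is set to
#' \eqn{y_{kj} = b^T x_{kj} + c + e_{kj}} with Gaussian noise. The default
#' cohort mirrors the study design: 17 animals (4 control, 13 SE: six
#' kainate plus seven pilocarpine survivors) by 4 regions = 68 rows.
#'
#' @param K number of animals.
#' @param J number of regions (taken from \code{eigenParams} regions).
#' @param groupLabels character vector of length K ("control"/"SE").
#' @param regionNames character vector of length J.
#' @param eigenParams data.frame as \code{\link{defaultEigenvalueParams}}.
#' @param b named numeric vector of true coefficients over
#'   c(FA, RD, MD, CP, CS); may be a matrix with one row per response.
#' @param c0 true intercept (vector if multiple responses).
#' @param noiseSd Gaussian noise SD per response; ignored when
#'   \code{targetR2} is given.
#' @param targetR2 optional population R-squared; when set, the noise SD is
#'   calibrated from the realised signal variance as
#'   \code{sd(signal) * sqrt((1 - R2) / R2)}.
#' @param responseNames names for the response columns.
#' @param seed integer seed.
#' @return list of class \code{CohortSpec}.
#' @export
cohortSpec <- function(K = 17, J = 4,
                       groupLabels = rep(c("control", "SE"), c(4, K - 4)),
                       regionNames = c("cc", "layerV", "layerVI", "CA3b"),
                       eigenParams = defaultEigenvalueParams(),
                       b = c(FA = 0.9, RD = -0.8, MD = 0.4,
                             CP = 0.5, CS = -0.6),
                       c0 = 0.3, noiseSd = 0.05, targetR2 = NULL,
                       responseNames = NULL, seed = 1) {
  if (is.null(dim(b))) b <- matrix(b, nrow = 1,
                                   dimnames = list(NULL, names(b)))
  stopifnot(ncol(b) == 5L,
            all(colnames(b) == c("FA", "RD", "MD", "CP", "CS")))
  if (is.null(responseNames))
    responseNames <- if (nrow(b) == 1L) "y" else
      paste0("y", seq_len(nrow(b)))
  spec <- list(K = as.integer(K), J = as.integer(J),
               groupLabels = groupLabels,
               regionNames = regionNames[seq_len(J)],
               eigenParams = eigenParams, b = b,
               c0 = rep_len(c0, nrow(b)),
               noiseSd = rep_len(noiseSd, nrow(b)),
               targetR2 = targetR2, responseNames = responseNames,
               seed = seed)
  stopifnot(length(spec$groupLabels) == spec$K,
            all(spec$groupLabels %in% eigenParams$group),
            all(spec$regionNames %in% eigenParams$region))
  class(spec) <- "CohortSpec"
  spec
}

#' Generate a synthetic cohort table
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return A \linkS4class{CohortTable}; \code{cohortTruth()} holds the true
#'   \code{b}, \code{c}, and realised \code{noiseSd}.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "CohortSpec"))
  withr::with_seed(streamSeed(spec$seed, 404L), {
    rows <- expand.grid(animal = seq_len(spec$K),
                        region = spec$regionNames,
                        stringsAsFactors = FALSE)
    n <- nrow(rows)
    lam <- matrix(NA_real_, n, 3)
    for (i in seq_len(n)) {
      g <- spec$groupLabels[rows$animal[i]]
      pr <- spec$eigenParams[spec$eigenParams$group == g &
                             spec$eigenParams$region == rows$region[i], ]
      repeat {  # reject non-positive draws, then enforce the sort order
        tr <- rnorm(3, mean = c(pr$m1, pr$m2, pr$m3),
                    sd = c(pr$s1, pr$s2, pr$s3))
        if (all(tr > 0)) break
      }
      lam[i, ] <- sort(tr, decreasing = TRUE)
    }
    sm <- computeScalarMetrics(lam[, 1], lam[, 2], lam[, 3])
    X <- as.matrix(sm[, c("FA", "RD", "MD", "CP", "CS")])
    d <- data.frame(animal_id = sprintf("A%02d", rows$animal),
                    group = spec$groupLabels[rows$animal],
                    region = rows$region,
                    lambda1 = lam[, 1], lambda2 = lam[, 2],
                    lambda3 = lam[, 3], sm)
    noiseSd <- spec$noiseSd
    for (r in seq_len(nrow(spec$b))) {
      signal <- as.numeric(X %*% spec$b[r, ]) + spec$c0[r]
      if (!is.null(spec$targetR2)) {
        stopifnot(spec$targetR2 > 0, spec$targetR2 < 1)
        noiseSd[r] <- sd(signal) *
          sqrt((1 - spec$targetR2) / spec$targetR2)
      }
      y <- signal + if (noiseSd[r] > 0) rnorm(n, 0, noiseSd[r]) else 0
      d[[spec$responseNames[r]]] <- y
    }
    CohortTable(d, truth = list(b = spec$b, c = spec$c0,
                                noiseSd = noiseSd,
                                responses = spec$responseNames))
  })
}
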