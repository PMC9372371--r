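# Orchestration: ROI extraction, cohort assembly, and an end-to-end
# synthetic run wiring phantom generation -> image quantification -> DTI
# metrics -> cohort assembly -> estimation statistics -> predictive model.

.REGION_VOCAB <- c("cc", "layerV", "layerVI", "CA3b")

#' Mean of a map over an ROI mask
#'
#' Missing-aware summary of a scalar image or volume over a region of
#' interest; DTI-histology correspondence in this pipeline is by region
#' label, so the per-region scalar is simply the masked summary.
#'
#' @param map numeric matrix or array.
#' @param roi logical mask of the same dimensions.
#' @param summary \code{"mean"} (default) or \code{"median"}.
#' @return scalar.
#' @export
extractRoiValue <- function(map, roi, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (!identical(dim(map), dim(roi))) stop("mask outside map bounds")
  v <- map[as.logical(roi)]
  if (!length(v)) stop("empty mask")
  v <- v[is.finite(v)]
  if (!length(v)) stop("mask covers only missing voxels")
  if (summary == "mean") mean(v) else median(v)
}

#' Assemble a cohort table from per-(animal, region) value lists
#'
#' Joins DTI-level and histology-level scalar values into one row per
#' (animal, region) pair of the manifest. Pairs missing from a value table
#' yield \code{NA} entries and are reported in the \code{gaps} attribute.
#'
#' @param dtiValues data.frame with columns animal_id, group, region,
#'   lambda1..3 (eigenvalues); the seven DTI scalars are computed from
#'   them.
#' @param histoValues data.frame with columns animal_id, region, plus one
#'   column per histological parameter.
#' @param manifest data.frame with columns animal_id, group, region
#'   listing every expected pair; defaults to the pairs present in
#'   \code{dtiValues}.
#' @return A \linkS4class{CohortTable}; attribute \code{gaps} lists
#'   (animal, region) pairs with missing histology.
#' @export
assembleCohort <- function(dtiValues, histoValues, manifest = NULL) {
  if (is.null(manifest))
    manifest <- dtiValues[, c("animal_id", "group", "region")]
  key <- paste(manifest$animal_id, manifest$region)
  if (anyDuplicated(key))
    stop("duplicate (animal, region) entries in manifest")
  if (anyDuplicated(paste(dtiValues$animal_id, dtiValues$region)))
    stop("duplicate (animal, region) entries in dtiValues")
  if (anyDuplicated(paste(histoValues$animal_id, histoValues$region)))
    stop("duplicate (animal, region) entries in histoValues")
  d <- merge(manifest, dtiValues, all.x = TRUE,
             by = c("animal_id", "group", "region"))
  sm <- computeScalarMetrics(d$lambda1, d$lambda2, d$lambda3)
  d <- cbind(d, sm)
  d <- merge(d, histoValues, all.x = TRUE,
             by = c("animal_id", "region"), sort = FALSE)
  d <- d[order(d$animal_id, d$region), ]
  rownames(d) <- NULL
  histoCols <- setdiff(names(histoValues), c("animal_id", "region"))
  gapRows <- !stats::complete.cases(d[, histoCols, drop = FALSE])
  ct <- CohortTable(d)
  attr(ct, "gaps") <- d[gapRows, c("animal_id", "region")]
  ct
}

#' Configuration for an end-to-end synthetic run
#'
#' Schema-validated bundle of sizes, per-region thresholds, and seeds for
#' \code{\link{runAll}}. The defaults keep the run small enough for
#' interactive use; region names must come from the configured vocabulary
#' (cc, layerV, layerVI, CA3b).
#'
#' @param nControl,nSE numbers of control and SE animals.
#' @param regions character vector of region names.
#' @param imageSize phantom edge in pixels for the histology stages.
#' @param nPerm permutations for the effect-size table.
#' @param nBoot bootstrap resamples for effect-size CIs.
#' @param seed global integer seed.
#' @param outputDir optional directory; when set, all tables are written
#'   there as CSV.
#' @return list of class \code{RunConfig}.
#' @export
runConfig <- function(nControl = 4, nSE = 4,
                      regions = c("cc", "CA3b"),
                      imageSize = 160, nPerm = 2000, nBoot = 1000,
                      seed = 1, outputDir = NULL) {
  if (!all(regions %in% .REGION_VOCAB))
    stop("unknown region name(s): ",
         paste(setdiff(regions, .REGION_VOCAB), collapse = ", "),
         " (vocabulary: ", paste(.REGION_VOCAB, collapse = ", "), ")")
  stopifnot(nControl >= 2, nSE >= 2, imageSize >= 96)
  structure(list(nControl = nControl, nSE = nSE, regions = regions,
                 imageSize = imageSize, nPerm = nPerm, nBoot = nBoot,
                 seed = seed, outputDir = outputDir),
            class = "RunConfig")
}

#' End-to-end synthetic pipeline run
#'
#' Generates a synthetic cohort: per (animal, region), an eigenvalue
#' triple (DTI side) and three phantom micrographs (Nissl-like,
#' fiber-texture, astrocyte-like) whose generating parameters differ by
#' group, quantifies the images (cell density, anisotropy index, skeleton
#' morphometry), assembles the cohort table, and runs the estimation
#' statistics and the predictive model with both cross-validation schemes.
#' Deterministic under a fixed seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @return list of class \code{RunReport}: \code{cohort}
#'   (\linkS4class{CohortTable}), \code{effects} (effect-size table),
#'   \code{model} (model-evaluation table), \code{loro} (per-region
#'   held-out R), \code{log} (run provenance: seed, config, package
#'   version).
#' @export
runAll <- function(config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"))
  K <- config$nControl + config$nSE
  groups <- rep(c("control", "SE"), c(config$nControl, config$nSE))
  eig <- defaultEigenvalueParams()
  rows <- expand.grid(animal = seq_len(K), region = config$regions,
                      stringsAsFactors = FALSE)
  dti <- NULL; histo <- NULL
  for (i in seq_len(nrow(rows))) {
    k <- rows$animal[i]; rg <- rows$region[i]; g <- groups[k]
    sd0 <- streamSeed(config$seed, 9000L + i)
    pr <- eig[eig$group == g & eig$region == rg, ]
    lam <- withr::with_seed(sd0, {
      repeat {
        tr <- rnorm(3, c(pr$m1, pr$m2, pr$m3), c(pr$s1, pr$s2, pr$s3))
        if (all(tr > 0)) break
      }
      sort(tr, decreasing = TRUE)
    })
    se <- g == "SE"
    # group-dependent phantom parameters: SE has more cells (gliosis),
    # more coherent fiber texture in CA3b, and bushier astrocytes
    nis <- generateNissl(nisslPhantomSpec(
      imageSize = config$imageSize, pixelSize = 1,
      nCells = round(config$imageSize^2 / 1000 * if (se) 1.5 else 1),
      noiseSd = 6, seed = sd0 + 1L))
    fib <- generateFibers(fiberPhantomSpec(
      imageSize = config$imageSize, pixelSize = 1,
      dispersionKappa = if (se && rg == "CA3b") 16 else 4,
      nFibers = 60, noiseSd = 6, seed = sd0 + 2L))
    astPar <- withr::with_seed(sd0 + 4L, list(
      nSomata = sample(2:3, 1),
      branchesPerSoma = sample(3:4, 1),
      depth = if (se) sample(1:2, 1, prob = c(0.2, 0.8))
              else sample(1:2, 1, prob = c(0.8, 0.2))))
    ast <- generateAstrocytes(astroPhantomSpec(
      imageSize = max(384, config$imageSize),
      nSomata = astPar$nSomata,
      branchesPerSoma = astPar$branchesPerSoma,
      branchingDepth = astPar$depth, seed = sd0 + 3L))
    cd <- countCells(nis$image)
    ai <- micrographAI(fib$image)
    sk <- skeletonizeAndAnalyze(ast$truth$mask,
                                pixelSize = pixelSize(ast$image))
    dti <- rbind(dti, data.frame(
      animal_id = sprintf("A%02d", k), group = g, region = rg,
      lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3]))
    histo <- rbind(histo, data.frame(
      animal_id = sprintf("A%02d", k), region = rg,
      CD = cd$CD, AI = ai$AI,
      branches = sk$metrics$branches,
      branch_length = sk$metrics$branchLength,
      endpoint_voxels = sk$metrics$endpointVoxels,
      average_length = sk$metrics$averageLength))
  }
  cohort <- assembleCohort(dti, histo)
  params <- c("CD", "AI", "branches", "branch_length",
              "endpoint_voxels", "average_length")
  effects <- effectSizeTable(cohort, params, nBoot = config$nBoot,
                             nPerm = config$nPerm, seed = config$seed)
  model <- modelEvaluationTable(cohort, params, nBoot = 0)
  loro <- if (length(config$regions) >= 2)
    lapply(stats::setNames(params, params),
           function(p) loroCv(cohort, p)$perRegion)
  else NULL
  log <- list(seed = config$seed, config = unclass(config),
              packageVersion =
                as.character(utils::packageVersion("dtihisto")),
              timestamp = format(Sys.time(), tz = "UTC"))
  report <- list(cohort = cohort, effects = effects, model = model,
                 loro = loro, log = log)
  class(report) <- "RunReport"
  if (!is.null(config$outputDir)) {
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohortData(cohort),
                     file.path(config$outputDir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(effects,
                     file.path(config$outputDir, "effects.csv"),
                     row.names = FALSE)
    utils::write.csv(model, file.path(config$outputDir, "model.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed ", x$log$seed, ")\n", sep = "")
  show(x$cohort)
  cat("Top effects by |d|:\n")
  ef <- x$effects[order(-abs(x$effects$d)), ]
  print(head(ef[, c("parameter", "region", "d", "q", "band")], 5),
        row.names = FALSE)
  cat("Model evaluation:\n")
  print(x$model[, c("response", "R2", "R2adj", "Rcv", "Q2")],
        row.names = FALSE)
  invisible(x)
}
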