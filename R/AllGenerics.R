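#' @rdname Micrograph-class
#' @param object,x a \linkS4class{Micrograph}
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname Micrograph-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname CohortTable-class
#' @param x a \linkS4class{CohortTable}
#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @rdname CohortTable-class
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))

#' @describeIn Micrograph-class pixel matrix accessor
#' @export
setMethod("pixels", "Micrograph", function(x) x@pixels)

#' @describeIn Micrograph-class pixel size accessor (um/pixel)
#' @export
setMethod("pixelSize", "Micrograph", function(x) x@pixelSize)

#' @describeIn Micrograph-class image dimensions
#' @export
setMethod("dim", "Micrograph", function(x) dim(x@pixels))

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("Micrograph %d x %d px, %.4g um/px (%.1f x %.1f um)\n",
              d[1], d[2], object@pixelSize,
              d[1] * object@pixelSize, d[2] * object@pixelSize))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@pixels), max(object@pixels)))
})

#' @describeIn CohortTable-class underlying data.frame
#' @export
setMethod("cohortData", "CohortTable", function(x) x@data)

#' @describeIn CohortTable-class generating truth (synthetic cohorts)
#' @export
setMethod("cohortTruth", "CohortTable", function(x) x@truth)

#' @describeIn CohortTable-class number of rows and columns
#' @export
setMethod("dim", "CohortTable", function(x) dim(x@data))

setMethod("show", "CohortTable", function(object) {
  d <- object@data
  cat(sprintf("CohortTable: %d rows (%d animals x %d regions present)\n",
              nrow(d), length(unique(d$animal_id)),
              length(unique(d$region))))
  histo <- setdiff(names(d), c("animal_id", "group", "region",
                               "lambda1", "lambda2", "lambda3",
                               "FA", "AD", "RD", "MD", "CL", "CP", "CS"))
  cat("  histology columns:", paste(histo, collapse = ", "), "\n")
  if (length(object@truth))
    cat("  synthetic: true coefficients recorded in cohortTruth()\n")
})

setMethod("show", "StructureTensorField", function(object) {
  d <- dim(object@Jxx)
  cat(sprintf("StructureTensorField %d x %d px", d[1], d[2]))
  cfg <- object@config
  if (length(cfg))
    cat(sprintf(" (deriv sigma %g, kernel %d, integration sigma %g)",
                cfg$derivativeSigma, cfg$kernelSize, cfg$integrationSigma))
  cat("\n")
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf(
    "SkeletonGraph: %d skeleton voxels, %d branches, %d junctions\n",
    sum(object@skeleton), nrow(object@branches), nrow(object@junctions)))
})
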