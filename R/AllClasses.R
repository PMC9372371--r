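#' Micrograph: a single-channel 8-bit histology image with physical pixel size
#'
#' Container for one grayscale micrograph. Pixel values live on the 0-255
#' scale (stored as numeric for arithmetic convenience); \code{pixelSize} is
#' the pixel edge length in micrometres, e.g. 0.114 um for the acquisition
#' resolution of 0.013 um^2 per pixel typical of high-magnification
#' brightfield tiles.
#'
#' @slot pixels numeric matrix of intensities in [0, 255].
#' @slot pixelSize positive scalar, um per pixel edge.
#' @export
setClass("Micrograph",
  representation(pixels = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!is.numeric(object@pixels)) msg <- c(msg, "pixels must be numeric")
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a positive scalar (um/pixel)")
    px <- object@pixels
    if (any(!is.finite(px)) || any(px < 0) || any(px > 255))
      msg <- c(msg, "pixel values must be finite and within [0, 255]")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Micrograph
#'
#' @param pixels numeric matrix of 8-bit intensities (0-255).
#' @param pixelSize pixel edge length in micrometres.
#' @return A \linkS4class{Micrograph}.
#' @examples
#' m <- Micrograph(matrix(128, 16, 16), pixelSize = 0.114)
#' pixelSize(m)
#' @export
Micrograph <- function(pixels, pixelSize) {
  new("Micrograph", pixels = pixels, pixelSize = as.numeric(pixelSize))
}

#' Pixelwise 2D structure-tensor field
#'
#' Window-integrated structure tensor per pixel: symmetric 2x2 matrices
#' stored as the three independent components. Eigenvalues are nonnegative
#' by construction (sum of outer products of gradients).
#'
#' @slot Jxx,Jxy,Jyy numeric matrices of identical dimension.
#' @slot config list with the derivative/integration parameters used.
#' @export
setClass("StructureTensorField",
  representation(Jxx = "matrix", Jxy = "matrix", Jyy = "matrix",
                 config = "list"),
  validity = function(object) {
    d <- dim(object@Jxx)
    if (!identical(d, dim(object@Jxy)) || !identical(d, dim(object@Jyy)))
      return("tensor component matrices must share dimensions")
    TRUE
  })

#' Classified skeleton with traced branches
#'
#' A one-pixel-wide 8-connected skeleton whose voxels are classified by their
#' number of skeleton neighbours: endpoint (< 2), slab (exactly 2), junction
#' (> 2). Adjacent junction voxels are merged into single junctions; branches
#' are slab paths connecting endpoint/junction nodes.
#'
#' @slot skeleton logical matrix, the thinned skeleton.
#' @slot voxelClass integer matrix: 0 background, 1 endpoint, 2 slab,
#'   3 junction.
#' @slot branches data.frame, one row per traced branch (component id,
#'   length in um, endpoint/junction attachments).
#' @slot junctions data.frame, one row per merged junction (component id,
#'   number of emanating branches).
#' @slot components integer matrix labelling 8-connected skeleton pieces.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("SkeletonGraph",
  representation(skeleton = "matrix", voxelClass = "matrix",
                 branches = "data.frame", junctions = "data.frame",
                 components = "matrix", pixelSize = "numeric"),
  validity = function(object) {
    if (!identical(dim(object@skeleton), dim(object@voxelClass)))
      return("skeleton and voxelClass must share dimensions")
    if (object@pixelSize <= 0) return("pixelSize must be positive")
    TRUE
  })

#' Cohort table of per-animal, per-region DTI and histology parameters
#'
#' One row per (animal, region) pair. Required columns: \code{animal_id},
#' \code{group}, \code{region}, eigenvalues \code{lambda1..3}, the seven DTI
#' scalars (FA, AD, RD, MD, CL, CP, CS), plus at least one histology
#' response column.
#'
#' @slot data data.frame with the columns above.
#' @slot truth list; for synthetic cohorts, the generating coefficients
#'   (\code{b}, \code{c}, \code{noiseSd}) are recorded here.
#' @export
setClass("CohortTable",
  representation(data = "data.frame", truth = "list"),
  validity = function(object) {
    need <- c("animal_id", "group", "region", "lambda1", "lambda2",
              "lambda3", "FA", "AD", "RD", "MD", "CL", "CP", "CS")
    missing <- setdiff(need, names(object@data))
    if (length(missing))
      return(paste("missing required columns:",
                   paste(missing, collapse = ", ")))
    key <- paste(object@data$animal_id, object@data$region)
    if (anyDuplicated(key))
      return("duplicate (animal_id, region) rows")
    TRUE
  })

#' Construct a CohortTable from a data.frame
#'
#' @param data data.frame with the required columns (see
#'   \linkS4class{CohortTable}).
#' @param truth optional list of generating parameters for synthetic cohorts.
#' @return A \linkS4class{CohortTable}.
#' @export
CohortTable <- function(data, truth = list()) {
  new("CohortTable", data = as.data.frame(data), truth = truth)
}
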