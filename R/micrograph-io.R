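#' Read a micrograph from TIFF or PNG
#'
#' Reads a single-channel (or first-channel) image and attaches the physical
#' pixel size. Multi-channel images are reduced to their first channel.
#'
#' @param path path to a .tif/.tiff or .png file.
#' @param pixelSize pixel edge length in micrometres.
#' @return A \linkS4class{Micrograph}.
#' @export
readMicrograph <- function(path, pixelSize) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  Micrograph(quantize8(arr * 255), pixelSize)
}

#' Write a micrograph to TIFF or PNG
#'
#' @param x a \linkS4class{Micrograph}.
#' @param path output path; format chosen by extension.
#' @return Invisibly, \code{path}.
#' @export
writeMicrograph <- function(x, path) {
  stopifnot(is(x, "Micrograph"))
  arr <- pixels(x) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    png = png::writePNG(arr, path),
    stop("unsupported image format: ", ext))
  invisible(path)
}

#' Read aligned eigenvalue maps from NIfTI files
#'
#' @param paths character vector of three NIfTI paths, in the order
#'   lambda1, lambda2, lambda3.
#' @return list of three numeric arrays with identical dimensions.
#' @export
readEigenvalueMaps <- function(paths) {
  stopifnot(length(paths) == 3L)
  maps <- lapply(paths, function(p) {
    arr <- RNifti::readNifti(p)
    array(as.numeric(arr), dim = dim(arr))
  })
  d <- dim(maps[[1]])
  if (!all(vapply(maps, function(m) identical(dim(m), d), logical(1))))
    stop("eigenvalue maps have mismatched dimensions")
  names(maps) <- c("lambda1", "lambda2", "lambda3")
  maps
}
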