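#' Scalar DTI metrics and Westin shape indices from tensor eigenvalues
#'
#' Computes the four scalar diffusion metrics and the three Westin
#' tensor-shape indices from sorted diffusion-tensor eigenvalues
#' (lambda1 >= lambda2 >= lambda3, any consistent diffusivity unit):
#' \deqn{MD = (\lambda_1+\lambda_2+\lambda_3)/3,\quad AD = \lambda_1,\quad
#'   RD = (\lambda_2+\lambda_3)/2}
#' \deqn{FA = \sqrt{1/2}\,
#'   \frac{\sqrt{(\lambda_1-\lambda_2)^2+(\lambda_2-\lambda_3)^2+
#'   (\lambda_3-\lambda_1)^2}}{\sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}}}
#' Westin indices use the trace-normalised convention
#' \eqn{CL = (\lambda_1-\lambda_2)/T}, \eqn{CP = 2(\lambda_2-\lambda_3)/T},
#' \eqn{CS = 3\lambda_3/T} with \eqn{T} the trace, under which
#' \eqn{CL + CP + CS = 1} and \eqn{AD = 3 MD - 2 RD} hold exactly.
#' The lambda1-normalised variant (\code{westinNorm = "lambda1"}) divides
#' the same numerators by \eqn{3\lambda_1} instead and does not sum to one.
#'
#' Negative eigenvalues (possible in noisy tensor fits) are rejected with an
#' error by default; \code{negatives = "clamp"} truncates them to zero
#' before computing.
#'
#' @param lambda1,lambda2,lambda3 numeric vectors of sorted eigenvalues.
#' @param westinNorm \code{"trace"} (default) or \code{"lambda1"}.
#' @param negatives \code{"error"} (default) or \code{"clamp"}.
#' @return data.frame with columns FA, AD, RD, MD, CL, CP, CS.
#' @examples
#' computeScalarMetrics(2, 1, 1)  # FA = 1/sqrt(6), CL = 0.25, CS = 0.75
#' @export
computeScalarMetrics <- function(lambda1, lambda2, lambda3,
                                 westinNorm = c("trace", "lambda1"),
                                 negatives = c("error", "clamp")) {
  westinNorm <- match.arg(westinNorm)
  negatives <- match.arg(negatives)
  n <- length(lambda1)
  stopifnot(length(lambda2) == n, length(lambda3) == n)
  if (any(!is.finite(c(lambda1, lambda2, lambda3))))
    stop("eigenvalues must be finite")
  if (any(lambda1 < lambda2 - 1e-12 * abs(lambda1)) ||
      any(lambda2 < lambda3 - 1e-12 * abs(lambda1)))
    stop("eigenvalues must be sorted lambda1 >= lambda2 >= lambda3")
  if (any(lambda3 < 0)) {
    if (negatives == "error")
      stop("negative eigenvalues; use negatives = \"clamp\" to truncate")
    lambda1 <- pmax(lambda1, 0)
    lambda2 <- pmax(lambda2, 0)
    lambda3 <- pmax(lambda3, 0)
  }
  tr <- lambda1 + lambda2 + lambda3
  if (any(tr <= 0))
    stop("zero trace: shape indices undefined")
  MD <- tr / 3
  AD <- lambda1
  RD <- (lambda2 + lambda3) / 2
  num <- sqrt((lambda1 - lambda2)^2 + (lambda2 - lambda3)^2 +
              (lambda3 - lambda1)^2)
  den <- sqrt(lambda1^2 + lambda2^2 + lambda3^2)
  FA <- sqrt(0.5) * num / den
  normd <- if (westinNorm == "trace") tr else 3 * lambda1
  CL <- (lambda1 - lambda2) / normd
  CP <- 2 * (lambda2 - lambda3) / normd
  CS <- 3 * lambda3 / normd
  data.frame(FA = FA, AD = AD, RD = RD, MD = MD, CL = CL, CP = CP, CS = CS)
}

#' Voxelwise DTI metric maps from aligned eigenvalue maps
#'
#' Applies \code{\link{computeScalarMetrics}} at every voxel of three
#' aligned eigenvalue maps. Voxels outside \code{mask}, or with zero trace
#' (background), are emitted as \code{NA} in every output map.
#'
#' @param eigenMaps list of three numeric arrays (lambda1, lambda2, lambda3)
#'   with identical dimensions.
#' @param mask optional logical array of the same dimensions.
#' @param ... passed to \code{\link{computeScalarMetrics}}.
#' @return named list of seven arrays: FA, AD, RD, MD, CL, CP, CS.
#' @export
metricsMap <- function(eigenMaps, mask = NULL, ...) {
  stopifnot(length(eigenMaps) == 3L)
  d <- dim(eigenMaps[[1]])
  if (!all(vapply(eigenMaps, function(m) identical(dim(m), d), logical(1))))
    stop("eigenvalue maps have mismatched dimensions")
  l1 <- as.numeric(eigenMaps[[1]])
  l2 <- as.numeric(eigenMaps[[2]])
  l3 <- as.numeric(eigenMaps[[3]])
  use <- is.finite(l1) & is.finite(l2) & is.finite(l3) & (l1 + l2 + l3 > 0)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d)) stop("mask dimensions mismatch")
    use <- use & as.logical(mask)
  }
  out <- lapply(seq_len(7L), function(i) {
    a <- rep(NA_real_, length(l1)); dim(a) <- d; a
  })
  names(out) <- c("FA", "AD", "RD", "MD", "CL", "CP", "CS")
  if (any(use)) {
    sm <- computeScalarMetrics(l1[use], l2[use], l3[use], ...)
    for (nm in names(out)) out[[nm]][use] <- sm[[nm]]
  }
  out
}
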