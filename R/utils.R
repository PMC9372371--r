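#' @import methods
#' @importFrom stats coef cor cor.test lm median pnorm predict qnorm quantile
#'   rnorm runif sd var p.adjust pf
#' @importFrom utils head
NULL

# Derive a per-operation seed from a global seed so that independent
# generator calls consume independent streams. Kept below 2^31-1.
streamSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) * 2654435761 + stream * 40503) %% 2147483647)
}

# Reflect-pad a matrix by `k` pixels on every side.
padReflect <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  if (k >= nr || k >= nc)
    stop("image smaller than required padding (", k, " px)")
  ri <- c(seq(k + 1L, 2L), seq_len(nr), seq(nr - 1L, nr - k))
  ci <- c(seq(k + 1L, 2L), seq_len(nc), seq(nc - 1L, nc - k))
  m[ri, ci, drop = FALSE]
}

# 2D convolution with reflective boundary handling; kernel must be odd-sized.
convolveReflect <- function(m, kern) {
  k <- (dim(kern) - 1L) %/% 2L
  stopifnot(all(dim(kern) %% 2L == 1L))
  p <- max(k)
  mp <- padReflect(m, p)
  out <- EBImage::filter2(mp, kern, boundary = "circular")
  out[(p + 1L):(p + nrow(m)), (p + 1L):(p + ncol(m)), drop = FALSE]
}

# 1D Gaussian (and derivative) kernels truncated to `size` taps.
gaussian1d <- function(size, sigma, deriv = FALSE) {
  stopifnot(size %% 2L == 1L, sigma > 0)
  x <- seq(-(size - 1L) / 2L, (size - 1L) / 2L)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (deriv) -x / sigma^2 * g else g
}

gaussianKernel2d <- function(sigma, size = NULL) {
  if (is.null(size)) size <- 2L * ceiling(3 * sigma) + 1L
  g <- gaussian1d(size, sigma)
  outer(g, g)
}

# Clip to [0,255] and round to 8-bit levels.
quantize8 <- function(m) {
  m <- round(m)
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

# Von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 yields
# the uniform distribution on the circle.
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  atan2(sin(out), cos(out))
}

# Circular variance of axial (orientation, mod pi) data via angle doubling.
circularVarianceAxial <- function(theta) {
  if (length(theta) == 0L) return(NA_real_)
  1 - Mod(mean(exp(2i * theta)))
}

# 8-connected Bresenham rasterization of a segment; returns (row, col) steps.
bresenham <- function(r0, c0, r1, c1) {
  r0 <- round(r0); c0 <- round(c0); r1 <- round(r1); c1 <- round(c1)
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- dr + dc + 1L
  rows <- integer(n); cols <- integer(n)
  i <- 0L
  repeat {
    i <- i + 1L
    rows[i] <- r0; cols[i] <- c0
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 <  dc) { err <- err + dc; r0 <- r0 + sr }
  }
  cbind(row = rows[seq_len(i)], col = cols[seq_len(i)])
}

# Polyline length of an ordered pixel path, in pixel units.
pathLengthPx <- function(rc) {
  if (nrow(rc) < 2L) return(0)
  sum(sqrt(diff(rc[, 1])^2 + diff(rc[, 2])^2))
}

# Shift a matrix by (dr, dc), filling exposed border with `fill`.
shiftMatrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# The eight (dr, dc) neighbour offsets, Moore neighbourhood.
MOORE <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1,  0,  1, -1, 1, -1, 0, 1))
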