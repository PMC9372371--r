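# Estimation-statistics layer: standardized effect sizes with BCa bootstrap
# confidence intervals, studentized permutation t-tests, and BH-FDR
# correction, applied per (parameter, region) across the cohort.

#' Cohen's d (pooled-SD standardized mean difference)
#'
#' \eqn{d = (\bar{x}_{t} - \bar{x}_{c}) / s_p} with
#' \eqn{s_p = \sqrt{((n_1-1)s_1^2 + (n_2-1)s_2^2)/(n_1+n_2-2)}}
#' (treated minus control; sample variances with n-1).
#'
#' @param control,treated numeric vectors, n >= 2 each.
#' @return scalar d.
#' @examples
#' cohensD(c(1, 2, 3), c(3, 4, 5))  # 2
#' @export
cohensD <- function(control, treated) {
  n1 <- length(control); n2 <- length(treated)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  sp <- sqrt(((n1 - 1) * var(control) + (n2 - 1) * var(treated)) /
             (n1 + n2 - 2))
  if (sp == 0) stop("zero pooled SD: effect size undefined")
  (mean(treated) - mean(control)) / sp
}

#' Effect-size magnitude band
#'
#' Conventional thresholds on |d|: >= 0.8 large, >= 0.5 medium, >= 0.2
#' small, else negligible.
#'
#' @param d numeric vector of effect sizes.
#' @return character vector.
#' @export
effectSizeBand <- function(d) {
  cut(abs(d), breaks = c(-Inf, 0.2, 0.5, 0.8, Inf),
      labels = c("negligible", "small", "medium", "large"),
      right = FALSE) |> as.character()
}

#' Bias-corrected and accelerated (BCa) bootstrap CI for a two-sample
#' statistic
#'
#' Stratified bootstrap (resampling within each group), bias correction
#' \eqn{z_0} from the fraction of bootstrap replicates below the point
#' estimate, and acceleration \eqn{a} from the jackknife skewness
#' (delete-one over all observations, within their group).
#'
#' @param control,treated numeric vectors.
#' @param statistic function(control, treated) -> scalar; default
#'   \code{\link{cohensD}}.
#' @param nBoot number of bootstrap resamples (>= 1000).
#' @param alpha two-sided miscoverage; 0.05 gives a 95\% interval.
#' @param seed integer seed.
#' @return named numeric c(low, high); degenerate data give a zero-width
#'   interval at the point estimate, with a warning.
#' @export
bcaCI <- function(control, treated, statistic = cohensD, nBoot = 5000,
                  alpha = 0.05, seed = 1) {
  stopifnot(nBoot >= 1000)
  est <- statistic(control, treated)
  n1 <- length(control); n2 <- length(treated)
  boots <- withr::with_seed(streamSeed(seed, 505L), {
    vapply(seq_len(nBoot), function(i) {
      b1 <- control[sample.int(n1, n1, replace = TRUE)]
      b2 <- treated[sample.int(n2, n2, replace = TRUE)]
      tryCatch(statistic(b1, b2), error = function(e) NA_real_)
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  if (length(boots) < nBoot / 2)
    warning("many degenerate bootstrap replicates")
  if (length(unique(boots)) <= 1L) {
    warning("degenerate bootstrap distribution; zero-width interval")
    return(c(low = est, high = est))
  }
  z0 <- qnorm(mean(boots < est))
  if (!is.finite(z0)) {
    warning("bias correction undefined; zero-width interval")
    return(c(low = est, high = est))
  }
  # jackknife over all observations (each deleted within its group)
  jack <- c(
    vapply(seq_len(n1), function(i) statistic(control[-i], treated),
           numeric(1)),
    vapply(seq_len(n2), function(i) statistic(control, treated[-i]),
           numeric(1)))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  zl <- qnorm(alpha / 2); zu <- qnorm(1 - alpha / 2)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  qs <- quantile(boots, probs = c(adj(zl), adj(zu)), names = FALSE,
                 type = 6)
  c(low = qs[1], high = qs[2])
}

#' Studentized two-sided permutation t-test
#'
#' Uses Welch's t as the studentized statistic; group labels are permuted
#' and the two-sided p-value is \eqn{(\#\{|t^*| \ge |t_{obs}|\} + 1) /
#' (n_{perm} + 1)} (add-one convention, so p is never 0). When the number
#' of distinct label assignments is small
#' (\code{choose(n1 + n2, n1) <= exhaustiveLimit}) all assignments are
#' enumerated instead and the p-value is exact (no add-one).
#'
#' @param control,treated numeric vectors, n >= 2 each.
#' @param nPerm number of sampled permutations (default 1e5).
#' @param seed integer seed.
#' @param exhaustiveLimit enumerate exhaustively when the total number of
#'   assignments does not exceed this.
#' @return list of class \code{PermutationTest}: \code{p} (add-one),
#'   \code{pRaw} (raw proportion), \code{tObs}, \code{nPerm},
#'   \code{exhaustive}.
#' @export
permutationTTest <- function(control, treated, nPerm = 1e5, seed = 1,
                             exhaustiveLimit = 20000) {
  n1 <- length(control); n2 <- length(treated)
  if (n1 < 2 || n2 < 2) stop("need at least 2 observations per group")
  pooled <- c(control, treated)
  if (length(unique(pooled)) == 1L)
    return(structure(list(p = 1, pRaw = 1, tObs = 0, nPerm = 0L,
                          exhaustive = TRUE),
                     class = "PermutationTest"))
  welch <- function(idx2) {
    x2 <- pooled[idx2]; x1 <- pooled[-idx2]
    se <- sqrt(var(x1) / n1 + var(x2) / n2)
    if (se == 0) return(0)
    (mean(x2) - mean(x1)) / se
  }
  tObs <- welch(seq.int(n1 + 1L, n1 + n2))
  nTot <- n1 + n2
  if (choose(nTot, n2) <= exhaustiveLimit) {
    combos <- utils::combn(nTot, n2)
    ts <- apply(combos, 2, welch)
    pRaw <- mean(abs(ts) >= abs(tObs) - 1e-12)
    return(structure(list(p = pRaw, pRaw = pRaw, tObs = tObs,
                          nPerm = ncol(combos), exhaustive = TRUE),
                     class = "PermutationTest"))
  }
  ts <- withr::with_seed(streamSeed(seed, 606L), {
    vapply(seq_len(nPerm), function(i)
      welch(sample.int(nTot, n2)), numeric(1))
  })
  hits <- sum(abs(ts) >= abs(tObs) - 1e-12)
  structure(list(p = (hits + 1) / (nPerm + 1), pRaw = hits / nPerm,
                 tObs = tObs, nPerm = as.integer(nPerm),
                 exhaustive = FALSE),
            class = "PermutationTest")
}

#' @export
print.PermutationTest <- function(x, ...) {
  cat(sprintf("Permutation t-test: t = %.3f, p = %.4g (%s, %d perms)\n",
              x$tObs, x$p,
              if (x$exhaustive) "exhaustive" else "sampled", x$nPerm))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j},
#' capped at 1, returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bhFdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Per-region, per-parameter effect-size table
#'
#' The driver behind group-comparison reporting: for every requested
#' parameter and region, computes Cohen's d (SE minus control, both
#' treatment models pooled as one SE group by their shared label), its BCa
#' bootstrap CI, the studentized permutation p-value, and BH-FDR q-values
#' adjusted within the table family (all rows of this call).
#'
#' @param cohort a \linkS4class{CohortTable} or data.frame.
#' @param parameters character vector of columns to analyse.
#' @param controlLabel,treatedLabel group labels (default "control"/"SE").
#' @param nBoot bootstrap resamples for the CI.
#' @param nPerm permutations for the p-value.
#' @param seed integer seed.
#' @return data.frame: parameter, region, n1, n2, d, ciLow, ciHigh, p, q,
#'   band.
#' @export
effectSizeTable <- function(cohort, parameters,
                            controlLabel = "control", treatedLabel = "SE",
                            nBoot = 5000, nPerm = 1e5, seed = 1) {
  d <- if (is(cohort, "CohortTable")) cohortData(cohort) else cohort
  stopifnot(all(parameters %in% names(d)))
  regions <- unique(d$region)
  rows <- expand.grid(parameter = parameters, region = regions,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(rows)), function(i) {
    sub <- d[d$region == rows$region[i], ]
    ctrl <- sub[[rows$parameter[i]]][sub$group == controlLabel]
    trt <- sub[[rows$parameter[i]]][sub$group == treatedLabel]
    na <- data.frame(parameter = rows$parameter[i],
                     region = rows$region[i],
                     n1 = length(ctrl), n2 = length(trt), d = NA_real_,
                     ciLow = NA_real_, ciHigh = NA_real_, p = NA_real_)
    dd <- tryCatch(cohensD(ctrl, trt), error = function(e) {
      warning("degenerate cell ", rows$parameter[i], " / ",
              rows$region[i], ": ", conditionMessage(e), call. = FALSE)
      NA_real_
    })
    if (!is.finite(dd)) return(na)
    ci <- suppressWarnings(bcaCI(ctrl, trt, nBoot = max(1000, nBoot),
                                 seed = streamSeed(seed, i)))
    pt <- permutationTTest(ctrl, trt, nPerm = nPerm,
                           seed = streamSeed(seed, 1000L + i))
    na$d <- dd; na$ciLow <- ci[1]; na$ciHigh <- ci[2]; na$p <- pt$p
    na
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- NA_real_
  ok <- is.finite(out$p)
  out$q[ok] <- bhFdr(out$p[ok])
  out$band <- NA_character_
  out$band[is.finite(out$d)] <- effectSizeBand(out$d[is.finite(out$d)])
  out
}
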