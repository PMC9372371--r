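# Multivariate DTI -> histology regression and cross-validation.
# The model is y_kj = b' x_kj + c + e_kj over all animals k and regions j
# concatenated, with predictors x = (FA, RD, MD, CP, CS). AD and CL are
# excluded by construction: AD = 3 MD - 2 RD and CL = 1 - CP - CS make the
# seven-parameter design singular.

.DTI_PREDICTORS <- c("FA", "RD", "MD", "CP", "CS")

asCohortDf <- function(table) {
  if (is(table, "CohortTable")) cohortData(table) else as.data.frame(table)
}

# Detect exact linear dependencies in the design and name them.
checkDesignRank <- function(X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    known <- c(
      if (all(c("AD", "MD", "RD") %in% colnames(X)))
        "AD = 3*MD - 2*RD",
      if (all(c("CL", "CP", "CS") %in% colnames(X)))
        "CL = 1 - CP - CS")
    stop("singular design: column(s) ", paste(dep, collapse = ", "),
         " are linearly dependent on the others",
         if (length(known)) paste0(" (identities: ",
                                   paste(known, collapse = "; "), ")"))
  }
  invisible(TRUE)
}

#' Adjusted R-squared
#'
#' \eqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1)}.
#'
#' @param R2 coefficient of determination.
#' @param n number of observations.
#' @param p number of predictors.
#' @return adjusted R-squared.
#' @examples
#' adjustedR2(0.822, 68, 5)  # 0.807
#' @export
adjustedR2 <- function(R2, n, p) 1 - (1 - R2) * (n - 1) / (n - p - 1)

#' F statistic of a fitted regression from its R-squared
#'
#' \eqn{F = (R^2/p) / ((1-R^2)/(n-p-1))}.
#'
#' @inheritParams adjustedR2
#' @return F statistic on (p, n - p - 1) degrees of freedom.
#' @export
regressionF <- function(R2, n, p) (R2 / p) / ((1 - R2) / (n - p - 1))

#' Fit the multivariate DTI -> histology regression
#'
#' Ordinary least squares of one histological response on the five DTI
#' predictors over all (animal, region) rows. Rows with missing values in
#' the used columns are dropped listwise. The 95\% CI for R-squared is an
#' accelerated (BCa) bootstrap resampling whole animals as blocks, since
#' rows within an animal are dependent.
#'
#' @param table a \linkS4class{CohortTable} or data.frame.
#' @param response name of the response column.
#' @param predictors predictor columns (default FA, RD, MD, CP, CS).
#'   Including AD or CL alongside their complements raises a singularity
#'   error naming the dependency.
#' @param nBoot bootstrap resamples for the R-squared CI; 0 skips the CI.
#' @param seed integer seed for the bootstrap.
#' @return list of class \code{RegressionResult}: \code{b} (named
#'   coefficients), \code{c} (intercept), \code{R2}, \code{R2adj},
#'   \code{F}, \code{pF}, \code{R2ci}, \code{n}, \code{p}, \code{fit}
#'   (the lm object).
#' @export
fitMultivariate <- function(table, response,
                            predictors = .DTI_PREDICTORS,
                            nBoot = 2000, seed = 1) {
  d <- asCohortDf(table)
  stopifnot(response %in% names(d), all(predictors %in% names(d)))
  use <- stats::complete.cases(d[, c(response, predictors)])
  d <- d[use, ]
  n <- nrow(d)
  p <- length(predictors)
  if (n <= p + 1) stop("not enough rows (", n, ") for ", p, " predictors")
  X <- as.matrix(d[, predictors])
  checkDesignRank(cbind(`(Intercept)` = 1, X))
  fml <- stats::reformulate(predictors, response)
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  R2 <- sm$r.squared
  Fv <- regressionF(R2, n, p)
  res <- list(b = coef(fit)[predictors], c = unname(coef(fit)[1]),
              R2 = R2, R2adj = adjustedR2(R2, n, p), F = Fv,
              pF = pf(Fv, p, n - p - 1, lower.tail = FALSE),
              R2ci = c(low = NA_real_, high = NA_real_),
              n = n, p = p, fit = fit)
  if (nBoot > 0) {
    res$R2ci <- clusterBootR2ci(d, response, predictors,
                                nBoot = nBoot, seed = seed)
  }
  class(res) <- "RegressionResult"
  res
}

# Animal-block accelerated bootstrap CI for R^2.
clusterBootR2ci <- function(d, response, predictors, nBoot = 2000,
                            alpha = 0.05, seed = 1) {
  animals <- unique(d$animal_id)
  K <- length(animals)
  fml <- stats::reformulate(predictors, response)
  statR2 <- function(ids) {
    dd <- do.call(rbind, lapply(ids, function(a) d[d$animal_id == a, ]))
    if (nrow(dd) <= length(predictors) + 1) return(NA_real_)
    summary(lm(fml, data = dd))$r.squared
  }
  est <- summary(lm(fml, data = d))$r.squared
  boots <- withr::with_seed(streamSeed(seed, 707L), {
    vapply(seq_len(nBoot), function(i)
      statR2(sample(animals, K, replace = TRUE)), numeric(1))
  })
  boots <- boots[is.finite(boots)]
  if (length(unique(boots)) <= 1L) return(c(low = est, high = est))
  z0 <- qnorm(mean(boots < est))
  if (!is.finite(z0)) return(c(low = est, high = est))
  jack <- vapply(seq_len(K), function(i) statR2(animals[-i]), numeric(1))
  jm <- mean(jack)
  denom <- sum((jm - jack)^2)^1.5
  a <- if (denom == 0) 0 else sum((jm - jack)^3) / (6 * denom)
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  qs <- quantile(boots, probs = c(adj(qnorm(alpha / 2)),
                                  adj(qnorm(1 - alpha / 2))),
                 names = FALSE, type = 6)
  c(low = qs[1], high = qs[2])
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf(
    "RegressionResult: R2 = %.3f (adj %.3f), F(%d, %d) = %.2f, n = %d\n",
    x$R2, x$R2adj, x$p, x$n - x$p - 1, x$F, x$n))
  if (is.finite(x$R2ci[1]))
    cat(sprintf("  R2 95%% CI (animal-block BCa): (%.3f, %.3f)\n",
                x$R2ci[1], x$R2ci[2]))
  invisible(x)
}

#' Univariate Pearson correlation between one DTI predictor and one
#' histological parameter
#'
#' Pooled over all rows; 95\% CI via the Fisher z transform
#' (\code{cor.test}).
#'
#' @param table a \linkS4class{CohortTable} or data.frame.
#' @param response,predictor column names.
#' @return list: \code{R}, \code{ci}, \code{R2}, \code{p}, \code{n}.
#' @export
pearsonUnivariate <- function(table, response, predictor) {
  d <- asCohortDf(table)
  x <- d[[predictor]]; y <- d[[response]]
  use <- is.finite(x) & is.finite(y)
  x <- x[use]; y <- y[use]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in ", if (sd(x) == 0) predictor else response)
  ct <- cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), ci = unname(ct$conf.int),
       R2 = unname(ct$estimate)^2, p = ct$p.value, n = length(x))
}

#' Univariate correlation grid with BH-FDR over the family
#'
#' @param table a \linkS4class{CohortTable} or data.frame.
#' @param responses character vector of histology columns.
#' @param predictors character vector of DTI columns.
#' @return data.frame: response, predictor, R, ciLow, ciHigh, R2, p, q.
#' @export
pearsonTable <- function(table, responses,
                         predictors = .DTI_PREDICTORS) {
  grid <- expand.grid(response = responses, predictor = predictors,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    r <- pearsonUnivariate(table, grid$response[i], grid$predictor[i])
    data.frame(response = grid$response[i],
               predictor = grid$predictor[i], R = r$R,
               ciLow = r$ci[1], ciHigh = r$ci[2], R2 = r$R2, p = r$p)
  })
  out <- do.call(rbind, res)
  out$q <- bhFdr(out$p)
  out
}

#' Cross-validated coefficient of determination Q-squared
#'
#' \eqn{Q^2 = 1 - \sum (y - \hat{y})^2 / \sum (y - \bar{y})^2} with
#' \eqn{\bar{y}} the mean of the true values over all rows. Equals 1 only
#' for perfect prediction; 0 for predicting the mean; negative when
#' held-out predictions are worse than the mean.
#'
#' @param y true values.
#' @param yhat held-out predictions.
#' @return scalar Q-squared.
#' @export
q2Score <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  1 - mean((y - yhat)^2) / mean((y - mean(y))^2)
}

#' Leave-one-animal-out cross-validation
#'
#' For each animal, the model is fitted on the remaining animals' rows
#' (all regions) and the held-out animal's rows are predicted. All held-out
#' predictions are pooled; reported are the cross-validated Pearson R
#' between predictions and truths, and \code{\link{q2Score}}.
#'
#' @inheritParams fitMultivariate
#' @return list of class \code{CvResult}: \code{Rcv}, \code{Q2},
#'   \code{predictions} (data.frame animal_id, region, y, yhat).
#' @export
loaoCv <- function(table, response, predictors = .DTI_PREDICTORS) {
  d <- asCohortDf(table)
  use <- stats::complete.cases(d[, c(response, predictors)])
  d <- d[use, ]
  animals <- unique(d$animal_id)
  if (length(animals) < 3) stop("need at least 3 animals")
  fml <- stats::reformulate(predictors, response)
  preds <- lapply(animals, function(a) {
    train <- d[d$animal_id != a, ]
    test <- d[d$animal_id == a, ]
    X <- cbind(1, as.matrix(train[, predictors]))
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient training design when holding out animal ", a)
    fit <- lm(fml, data = train)
    data.frame(animal_id = a, region = test$region,
               y = test[[response]],
               yhat = unname(predict(fit, newdata = test)))
  })
  pr <- do.call(rbind, preds)
  out <- list(Rcv = cor(pr$y, pr$yhat), Q2 = q2Score(pr$y, pr$yhat),
              predictions = pr)
  class(out) <- "CvResult"
  out
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("CvResult: cross-validated R = %.3f, Q2 = %.3f (%d rows)\n",
              x$Rcv, x$Q2, nrow(x$predictions)))
  invisible(x)
}

#' Leave-one-brain-region-out cross-validation
#'
#' For each region, the model is fitted on the other regions' rows and the
#' held-out region's rows are predicted. Reports the Pearson R on each
#' held-out region and the pooled R (and Q-squared) over the concatenated
#' held-out predictions of all folds.
#'
#' @inheritParams fitMultivariate
#' @return list of class \code{LoroResult}: \code{perRegion} (data.frame
#'   region, R, n), \code{pooledR}, \code{pooledQ2}, \code{predictions}.
#' @export
loroCv <- function(table, response, predictors = .DTI_PREDICTORS) {
  d <- asCohortDf(table)
  use <- stats::complete.cases(d[, c(response, predictors)])
  d <- d[use, ]
  regions <- unique(d$region)
  if (length(regions) < 2) stop("need at least 2 regions")
  fml <- stats::reformulate(predictors, response)
  preds <- lapply(regions, function(rg) {
    train <- d[d$region != rg, ]
    test <- d[d$region == rg, ]
    X <- cbind(1, as.matrix(train[, predictors]))
    if (qr(X)$rank < ncol(X))
      stop("rank-deficient training design when holding out region ", rg)
    fit <- lm(fml, data = train)
    data.frame(animal_id = test$animal_id, region = rg,
               y = test[[response]],
               yhat = unname(predict(fit, newdata = test)))
  })
  pr <- do.call(rbind, preds)
  perRegion <- do.call(rbind, lapply(regions, function(rg) {
    sub <- pr[pr$region == rg, ]
    data.frame(region = rg, R = cor(sub$y, sub$yhat), n = nrow(sub))
  }))
  out <- list(perRegion = perRegion, pooledR = cor(pr$y, pr$yhat),
              pooledQ2 = q2Score(pr$y, pr$yhat), predictions = pr)
  class(out) <- "LoroResult"
  out
}

#' @export
print.LoroResult <- function(x, ...) {
  cat(sprintf("LoroResult: pooled held-out R = %.3f, Q2 = %.3f\n",
              x$pooledR, x$pooledQ2))
  print(x$perRegion, row.names = FALSE)
  invisible(x)
}

#' Full model-evaluation table across responses
#'
#' One row per histological response: multivariate R2 (with adjusted R2
#' and F), leave-one-animal-out cross-validated R and Q2.
#'
#' @param table a \linkS4class{CohortTable} or data.frame.
#' @param responses character vector of response columns.
#' @param nBoot bootstrap resamples for the R2 CI (0 to skip).
#' @param seed integer seed.
#' @return data.frame: response, R2, ciLow, ciHigh, R2adj, F, pF, q,
#'   Rcv, Q2.
#' @export
modelEvaluationTable <- function(table, responses, nBoot = 0, seed = 1) {
  res <- lapply(responses, function(rs) {
    fit <- fitMultivariate(table, rs, nBoot = nBoot, seed = seed)
    cv <- loaoCv(table, rs)
    data.frame(response = rs, R2 = fit$R2, ciLow = fit$R2ci[1],
               ciHigh = fit$R2ci[2], R2adj = fit$R2adj, F = fit$F,
               pF = fit$pF, Rcv = cv$Rcv, Q2 = cv$Q2)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$q <- bhFdr(out$pF)
  out
}
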