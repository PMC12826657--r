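#' Fit the covariate-only null model
#'
#' Fits the null (no predictor effect) model of the response on the
#' nuisance covariates and returns the quantities every kernel statistic
#' consumes: fitted values, residuals and dispersion weights.  Gaussian
#' responses are fit by least squares; Bernoulli responses by logistic
#' regression (IRLS via [stats::glm.fit()]).
#'
#' The caller is responsible for including an intercept column in
#' \code{X}.  Residuals are orthogonal to the column space of \code{X}
#' (the score equations at the null MLE), which is what licenses the
#' residual-permutation null downstream.
#'
#' @param y numeric response vector; for \code{family = "bernoulli"} the
#'   values must be coded 0/1 and both classes must be present.
#' @param X numeric covariate matrix (n x m), full column rank, m < n,
#'   including the intercept.
#' @param family \code{"gaussian"} or \code{"bernoulli"}.
#' @return a [NullFit-class].  For the Gaussian family \code{sigma2} holds
#'   the unbiased residual variance RSS/(n - m), used by the analytic
#'   (chi-square mixture) local p-values.
#' @examples
#' y <- c(1, 2, 3, 4)
#' fitNull(y, cbind(1, 0:3))
#' @export
fitNull <- function(y, X, family = c("gaussian", "bernoulli")) {
  family <- match.arg(family)
  if (!is.numeric(y) || anyNA(y))
    stop("response must be numeric with no missing values")
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations")
  X <- as.matrix(X)
  if (!is.numeric(X) || anyNA(X)) stop("covariate matrix must be numeric with no missing values")
  if (nrow(X) != n) stop("covariate matrix rows must match response length")
  m <- ncol(X)
  if (m >= n) stop("need fewer covariates than observations (m < n)")
  .checkFullRank(X)

  if (family == "gaussian") .fitNullGaussian(y, X) else .fitNullBinomial(y, X)
}

## rank check naming the offending (pivoted-out) columns
.checkFullRank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- qx$pivot[seq.int(qx$rank + 1L, ncol(X))]
    nm <- colnames(X)
    bad <- if (is.null(nm)) paste0("column ", bad) else nm[bad]
    stop("covariate matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  invisible(qx)
}

.fitNullGaussian <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  res <- as.numeric(fit$residuals)
  new("NullFit",
      fitted = as.numeric(fit$fitted.values),
      residuals = res,
      delta = rep(1, length(y)),
      sigma2 = sum(res^2) / (length(y) - ncol(X)),
      family = "gaussian")
}

.fitNullBinomial <- function(y, X, epsilon = 1e-8, maxit = 50L) {
  if (!all(y %in% c(0, 1)))
    stop("bernoulli response must be coded 0/1")
  if (length(unique(y)) < 2L)
    stop("bernoulli response must contain both classes")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = epsilon,
                                                maxit = maxit))
  )
  if (!fit$converged)
    stop("logistic null fit did not converge within ", maxit, " iterations")
  mu <- as.numeric(fit$fitted.values)
  ## perfect separation: fitted probabilities pinned to 0/1 for a whole class
  if (all(mu[y == 1] > 1 - 1e-6) || all(mu[y == 0] < 1e-6))
    stop("perfect separation detected: logistic MLE does not exist")
  new("NullFit",
      fitted = mu,
      residuals = y - mu,
      delta = mu * (1 - mu),
      sigma2 = NA_real_,
      family = "bernoulli")
}

#' @describeIn NullFit-class fitted values
#' @param object,x a \code{NullFit}
#' @param ... ignored
#' @export
setMethod("fitted", "NullFit", function(object, ...) object@fitted)

#' @describeIn NullFit-class residuals y - fitted
#' @export
setMethod("residuals", "NullFit", function(object, ...) object@residuals)

#' @describeIn NullFit-class dispersion weights delta
#' @export
setMethod("dispersionWeights", "NullFit", function(x) x@delta)

#' @describeIn NullFit-class brief summary
#' @export
setMethod("show", "NullFit", function(object) {
  cat(sprintf("NullFit (%s family), n = %d\n",
              object@family, length(object@fitted)))
  if (identical(object@family, "gaussian"))
    cat(sprintf("  sigma2_hat = %.6g\n", object@sigma2))
  else
    cat(sprintf("  delta range = [%.4g, %.4g]\n",
                min(object@delta), max(object@delta)))
})
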