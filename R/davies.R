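## Tail probability of a positively weighted sum of independent 1-df
## chi-square variables, P(sum_k lambda_k X_k > x).
##
## Primary route: numerical inversion of the characteristic function
## (Imhof's integral, the same quantity the Davies algorithm evaluates),
## via stats::integrate.  Fallback when the integration fails or returns
## a value outside [0, 1]: the Liu-Tang-Zhang four-moment chi-square
## approximation.  The route taken is recorded in the "method" attribute.

#' Upper tail of a chi-square mixture
#'
#' @param lambda positive mixture weights (eigenvalues); nonpositive and
#'   numerically negligible weights are dropped.
#' @param x threshold.
#' @return \code{P(sum lambda_k chi^2_1 > x)}, with attribute
#'   \code{method} = \code{"imhof"} or \code{"moment"} (fallback).
#' @examples
#' chisqMixturePvalue(1, stats::qchisq(0.95, 1))  # 0.05
#' @export
chisqMixturePvalue <- function(lambda, x) {
  lambda <- lambda[lambda > max(lambda, 0) * 1e-12]
  if (!length(lambda) || all(lambda <= 0))
    stop("no positive mixture weights: degenerate null distribution")
  if (x <= 0) return(structure(1, method = "exact"))
  p <- tryCatch(.imhofTail(lambda, x), error = function(e) NA_real_)
  if (is.na(p) || p < -1e-8 || p > 1 + 1e-8) {
    p <- .liuTail(lambda, x)
    attr(p, "method") <- "moment"
    return(p)
  }
  p <- min(max(p, 1e-300), 1)
  attr(p, "method") <- "imhof"
  p
}

## Imhof (1961) integral: P(Q > x) = 1/2 + (1/pi) Int_0^inf sin(theta(u)) /
## (u rho(u)) du, theta(u) = sum(atan(lambda u))/2 - x u / 2,
## rho(u) = prod (1 + lambda^2 u^2)^(1/4).
.imhofTail <- function(lambda, x) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * x * u
    lrho <- 0.25 * colSums(log1p(outer(lambda^2, u^2)))
    out <- sin(theta) * exp(-lrho) / u
    out[!is.finite(out)] <- 0
    out
  }
  int <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10,
                          abs.tol = 1e-12, subdivisions = 2000L,
                          stop.on.error = TRUE)
  0.5 + int$value / pi
}

## Liu, Tang & Zhang (2009) four-moment approximation.
.liuTail <- function(lambda, x) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    ncp <- s1 * a^3 - a^2
    df <- a^2 - 2 * ncp
  } else {
    a <- 1 / s1
    ncp <- 0
    df <- c2^3 / c3^2
  }
  muX <- df + ncp; sigmaX <- sqrt(2 * (df + 2 * ncp))
  tstar <- (x - muQ) / sigmaQ
  min(max(stats::pchisq(tstar * sigmaX + muX, df = df, ncp = ncp,
                        lower.tail = FALSE), 1e-300), 1)
}

#' Analytic p-value of a scaled ROI statistic (Gaussian response)
#'
#' For a Gaussian response the scaled ROI statistic Q_k is a SKAT
#' quadratic form divided by a constant, so its null distribution is a
#' positively weighted mixture of 1-df chi-squares.  With P0 the
#' residual-forming projection for the covariates X and Z_k the ROI's
#' predictor columns, the mixture weights are the eigenvalues of
#' sigma2 * Z_k' P0 Z_k and the scaling constant is
#' c = tr(Z_k Z_k') = sum of squared masked predictor values.  The tail
#' probability P(sum lambda chi^2 > c * q) is evaluated by
#' [chisqMixturePvalue()].
#'
#' @param qObs observed scaled ROI statistic.
#' @param mask 1-based feature indices of the ROI.
#' @param Z predictor matrix (n x p).
#' @param X covariate matrix used by the null fit.
#' @param sigma2 Gaussian residual variance estimate from the null fit.
#' @return p-value with attribute \code{method}.
#' @seealso [runLaxKAT()] with \code{localMethod = "davies"}
#' @export
daviesPvalue <- function(qObs, mask, Z, X, sigma2) {
  Z <- as.matrix(Z); X <- as.matrix(X)
  Zm <- Z[, mask, drop = FALSE]
  Zt <- stats::lm.fit(X, Zm)$residuals      # P0 Z_k
  Zt <- as.matrix(Zt)
  G <- crossprod(Zt)
  cc <- sum(Zm^2)                           # tr(Z_k Z_k'): Q_k denominator
  lam <- eigen((G + t(G)) / 2, symmetric = TRUE, only.values = TRUE)$values
  lam <- sigma2 * lam[lam > cc * 1e-10]     # relative to the trace scale
  if (!length(lam))
    stop("masked predictors lie in the covariate column space: ",
         "no variability under the null")
  chisqMixturePvalue(lam, cc * qObs)
}
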