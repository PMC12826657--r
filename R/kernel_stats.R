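## Kernel quadratic-form statistics.
##
## All statistics are computed by per-feature score accumulation
## (u = Z'r, then sums over features), never by materializing the n x n
## kernel Z W^2 Z' -- p ~ 1e4, n ~ 400 is the design point.

#' SKAT quadratic-form statistic
#'
#' Computes Q_SKAT = r' Z W^2 Z' r = sum_j w_j^2 (z_j' r)^2 for null-model
#' residuals r, predictors Z and a diagonal weight vector w.
#'
#' @param r numeric residual vector (length n).
#' @param Z numeric predictor matrix (n x p).
#' @param w nonnegative weight vector (length p), at least one positive
#'   entry; defaults to identity weights.
#' @return nonnegative scalar.
#' @examples
#' skatStatistic(c(1, -1, 2), cbind(c(1, 0, 1), c(0, 1, 1)), c(1, 2))
#' @export
skatStatistic <- function(r, Z, w = rep(1, ncol(Z))) {
  Z <- as.matrix(Z)
  stopifnot(length(r) == nrow(Z), length(w) == ncol(Z))
  if (any(w < 0) || !any(w > 0))
    stop("weights must be nonnegative with at least one positive entry")
  u <- drop(crossprod(Z, r))
  sum((w * u)^2)
}

#' Scaled ROI-specific statistic
#'
#' Computes Q_k = r' Z B_k^2 Z' r / tr(Delta Z B_k^2 Z') for the 0/1 mask
#' B_k of one ROI: the SKAT quadratic form restricted to the ROI's
#' features, scaled by its trace under the dispersion weights.  The
#' scaling makes statistics comparable across ROIs of different sizes and
#' predictor scales.
#'
#' @param r numeric residual vector.
#' @param Z numeric predictor matrix (n x p).
#' @param delta dispersion weights (length n); all 1 for Gaussian.
#' @param mask integer vector of 1-based feature indices (nonempty).
#' @param label optional ROI label used in error messages.
#' @return nonnegative scalar.
#' @export
roiStatistic <- function(r, Z, delta, mask, label = NULL) {
  Z <- as.matrix(Z)
  stopifnot(length(r) == nrow(Z), length(delta) == nrow(Z),
            length(mask) >= 1L)
  Zm <- Z[, mask, drop = FALSE]
  den <- sum(delta * rowSums(Zm^2))
  if (den <= 0)
    stop("zero trace denominator for ROI ",
         if (is.null(label)) paste(mask, collapse = ",") else label,
         ": all masked predictor values are zero")
  u <- drop(crossprod(Zm, r))
  sum(u^2) / den
}

## Shared per-feature accumulators: u_j = z_j' r and d_j = sum_i delta_i z_ij^2
.scoreAccumulators <- function(r, Z, delta) {
  list(u = drop(crossprod(Z, r)), d = drop(crossprod(Z^2, delta)))
}

#' @describeIn laxkatStatistic mutually exclusive (atlas) subspace: the
#'   maximum of the per-ROI statistics, with ties broken toward the
#'   smallest ROI index.
#' @export
setMethod("laxkatStatistic",
  signature(basis = "AtlasBasis"),
  function(r, Z, delta, basis) {
    Z <- as.matrix(Z)
    stopifnot(length(r) == nrow(Z), length(delta) == nrow(Z),
              ncol(Z) == basis@p)
    acc <- .scoreAccumulators(r, Z, delta)
    q <- length(basis@masks)
    perROI <- numeric(q)
    for (k in seq_len(q)) {
      idx <- basis@masks[[k]]
      den <- sum(acc$d[idx])
      if (den <= 0)
        stop("zero trace denominator for ROI ", basis@labels[k],
             ": all masked predictor values are zero")
      perROI[k] <- sum(acc$u[idx]^2) / den
    }
    names(perROI) <- basis@labels
    k <- which.max(perROI)   # first index on ties
    new("LaxKATStat", value = perROI[[k]], argmax = as.integer(k),
        perROI = perROI)
  })

#' @describeIn laxkatStatistic general subspace: the largest generalized
#'   eigenvalue of the reduced pencil (A, C), A = B' diag(u u) B,
#'   C = B' diag(d) B, with u = Z'r and d_j = sum_i delta_i z_ij^2 --
#'   the maximized Rayleigh quotient over W in the basis span.
#' @export
setMethod("laxkatStatistic",
  signature(basis = "GeneralBasis"),
  function(r, Z, delta, basis) {
    Z <- as.matrix(Z)
    B <- basis@basis
    stopifnot(length(r) == nrow(Z), length(delta) == nrow(Z),
              ncol(Z) == nrow(B))
    acc <- .scoreAccumulators(r, Z, delta)
    A <- crossprod(B, B * (acc$u^2))
    C <- crossprod(B, B * acc$d)
    R <- tryCatch(chol(C), error = function(e)
      stop("singular trace matrix C: degenerate basis/predictors"))
    Ri <- backsolve(R, diag(ncol(B)))
    M <- crossprod(Ri, A %*% Ri)
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    new("LaxKATStat", value = max(lam[1], 0), argmax = NA_integer_,
        perROI = numeric(0))
  })

#' @describeIn LaxKATStat-class print the statistic
#' @param object a \code{LaxKATStat}
#' @export
setMethod("show", "LaxKATStat", function(object) {
  cat(sprintf("LaxKAT statistic: %.6g\n", object@value))
  if (length(object@perROI))
    cat(sprintf("  attained by ROI %d (%s) of %d\n", object@argmax,
                names(object@perROI)[object@argmax], length(object@perROI)))
})
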