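## Independent oracles used across the suite.  These recompute quantities
## from their defining formulas (dense quadratic forms, random search over
## the kernel subspace, exhaustive enumeration, Newton-Raphson on the
## score equations) and never call the code paths they validate.

## Dense quadratic form r' (Z W^2 Z') r, forming the n x n kernel.
denseQuadForm <- function(r, Z, w) {
  K <- Z %*% diag(w^2, ncol(Z)) %*% t(Z)
  drop(t(r) %*% K %*% r)
}

## Dense trace tr(Delta Z W^2 Z').
denseTrace <- function(Z, delta, w) {
  K <- Z %*% diag(w^2, ncol(Z)) %*% t(Z)
  sum(diag(diag(delta, nrow(Z)) %*% K))
}

## Staged random-search maximization of the scaled quadratic form over
## unit-norm phi in the basis span: evaluates the defining ratio
## sum_j w_j^2 u_j^2 / sum_j w_j^2 d_j with w = B phi directly, for
## nPoints random phi (a global uniform stage followed by shrinking
## neighborhoods of the running best).
randomSearchLaxKAT <- function(r, Z, delta, B, nPoints = 1e5, stages = 5L) {
  u <- drop(t(Z) %*% r)
  d <- drop(t(Z^2) %*% delta)
  q <- ncol(B)
  per <- ceiling(nPoints / stages)
  best <- NULL
  bestVal <- -Inf
  radius <- NA_real_
  for (s in seq_len(stages)) {
    P <- matrix(rnorm(q * per), q, per)
    if (!is.na(radius)) P <- best + radius * P
    W <- B %*% P
    vals <- colSums(W^2 * u^2) / colSums(W^2 * d)
    i <- which.max(vals)
    if (vals[i] > bestVal) {
      bestVal <- vals[i]
      best <- P[, i]
    }
    radius <- if (is.na(radius)) 0.5 else radius / 8
  }
  bestVal
}

## All n! permutations of 1..n as columns (n small).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(cbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    rbind(rep(k, ncol(sub)), matrix(rest[sub], n - 1L))
  }))
}

## Logistic MLE by Newton-Raphson on the score equations.
logisticNewton <- function(X, y, tol = 1e-12, maxit = 100L) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    mu <- plogis(drop(X %*% b))
    g <- drop(t(X) %*% (y - mu))
    H <- t(X) %*% (X * (mu * (1 - mu)))
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}

## Random test instance: Gaussian response, one covariate plus intercept,
## iid normal predictors, q equal-ish ROIs.
randomInstance <- function(n, p, q) {
  labels <- sort(rep_len(paste0("r", seq_len(q)), p))
  list(y = rnorm(n),
       X = cbind(1, rnorm(n)),
       Z = matrix(rnorm(n * p), n, p),
       atlas = atlasFromLabels(labels))
}
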