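#' @import methods
NULL

#' Fitted covariate-only null model
#'
#' Container for the null (covariate-only) fit that all kernel statistics
#' consume: predicted responses, residuals, and the dispersion weights
#' \eqn{\delta_i} that scale the trace denominator of the ROI statistics.
#' For a Gaussian response \eqn{\delta_i = 1}; for a Bernoulli response
#' \eqn{\delta_i = \hat y_i (1 - \hat y_i)}.
#'
#' @slot fitted numeric vector of predicted responses \eqn{\hat y}.
#' @slot residuals numeric vector \eqn{y - \hat y}.
#' @slot delta numeric vector of dispersion weights.
#' @slot sigma2 Gaussian residual variance estimate, RSS/(n - m);
#'   \code{NA} for the Bernoulli family.
#' @slot family \code{"gaussian"} or \code{"bernoulli"}.
#'
#' @seealso [fitNull()]
#' @exportClass NullFit
setClass("NullFit",
  representation(
    fitted = "numeric",
    residuals = "numeric",
    delta = "numeric",
    sigma2 = "numeric",
    family = "character"
  )
)

setValidity("NullFit", function(object) {
  n <- length(object@fitted)
  msgs <- character()
  if (length(object@residuals) != n || length(object@delta) != n)
    msgs <- c(msgs, "fitted, residuals and delta must have equal length")
  if (!object@family %in% c("gaussian", "bernoulli"))
    msgs <- c(msgs, "family must be 'gaussian' or 'bernoulli'")
  if (identical(object@family, "gaussian") && any(object@delta != 1))
    msgs <- c(msgs, "gaussian family requires delta == 1")
  if (identical(object@family, "bernoulli") &&
      (any(object@delta <= 0) || any(object@delta > 0.25 + 1e-12)))
    msgs <- c(msgs, "bernoulli delta must lie in (0, 0.25]")
  if (length(msgs)) msgs else TRUE
})

#' Atlas parcellation basis
#'
#' A partition of feature (vertex) indices into q mutually exclusive,
#' nonempty ROI masks.  Equivalent to a basis of diagonal weight matrices
#' with disjoint supports, the setting in which the LaxKAT maximization
#' decouples into a maximum of per-ROI statistics.  Features assigned the
#' unassigned code belong to no mask and are excluded from all tests.
#'
#' @slot p total feature count.
#' @slot masks list of integer vectors, 1-based feature indices per ROI.
#' @slot labels character vector of ROI labels, parallel to \code{masks}.
#' @slot nUnassigned number of features excluded from every mask.
#'
#' @seealso [atlasFromLabels()], [asGeneralBasis()]
#' @exportClass AtlasBasis
setClass("AtlasBasis",
  representation(
    p = "integer",
    masks = "list",
    labels = "character",
    nUnassigned = "integer"
  )
)

setValidity("AtlasBasis", function(object) {
  msgs <- character()
  if (length(object@masks) != length(object@labels))
    msgs <- c(msgs, "masks and labels must be parallel")
  if (length(object@masks) == 0L)
    msgs <- c(msgs, "atlas must contain at least one ROI")
  idx <- unlist(object@masks, use.names = FALSE)
  if (length(idx)) {
    if (any(idx < 1L) || any(idx > object@p))
      msgs <- c(msgs, "mask indices must lie in 1..p")
    if (anyDuplicated(idx))
      msgs <- c(msgs, "masks must be pairwise disjoint")
  }
  if (any(lengths(object@masks) == 0L))
    msgs <- c(msgs, "every mask must be nonempty")
  if (anyDuplicated(object@labels))
    msgs <- c(msgs, "ROI labels must be unique")
  if (length(msgs)) msgs else TRUE
})

#' General diagonal-kernel basis
#'
#' A p x q matrix whose column k holds the diagonal of the k-th basis
#' element B_k of the kernel subspace.  Columns need not have disjoint
#' supports; in that general case the LaxKAT statistic is the largest
#' generalized eigenvalue of a reduced q x q pencil rather than a maximum
#' over per-ROI statistics.
#'
#' @slot basis numeric matrix (features x basis elements), columns
#'   linearly independent.
#'
#' @seealso [laxkatStatistic()], [validateExclusive()]
#' @exportClass GeneralBasis
setClass("GeneralBasis", representation(basis = "matrix"))

setValidity("GeneralBasis", function(object) {
  B <- object@basis
  msgs <- character()
  if (!is.numeric(B)) msgs <- c(msgs, "basis must be numeric")
  if (ncol(B) < 1L || ncol(B) > nrow(B))
    msgs <- c(msgs, "need 1 <= q <= p basis columns")
  if (is.numeric(B) && qr(B)$rank < ncol(B))
    msgs <- c(msgs, "basis columns must be linearly independent")
  if (length(msgs)) msgs else TRUE
})

#' Observed LaxKAT statistic
#'
#' The maximized, scaled quadratic-form statistic together with (for an
#' atlas subspace) the per-ROI statistics it maximizes over and the index
#' of the maximizing ROI.
#'
#' @slot value the statistic (nonnegative).
#' @slot argmax index of the maximizing basis element (smallest index on
#'   ties); \code{NA} for a general basis.
#' @slot perROI named numeric vector of per-ROI statistics Q_k
#'   (length 0 for a general basis).
#'
#' @exportClass LaxKATStat
setClass("LaxKATStat",
  representation(value = "numeric", argmax = "integer", perROI = "numeric")
)

setValidity("LaxKATStat", function(object) {
  msgs <- character()
  if (length(object@value) != 1L || is.na(object@value) || object@value < 0)
    msgs <- c(msgs, "value must be a single nonnegative number")
  if (length(object@perROI) > 0L) {
    if (abs(object@value - max(object@perROI)) >
        1e-8 * max(1, abs(object@value)))
      msgs <- c(msgs, "value must equal max(perROI)")
  }
  if (length(msgs)) msgs else TRUE
})

#' LaxKAT test result
#'
#' Global and ROI-level inference from one LaxKAT run: the observed
#' statistic, its permutation null draws, the global p-value, and raw plus
#' Holm-adjusted per-ROI p-values.
#'
#' @slot stat [LaxKATStat-class] observed statistic.
#' @slot globalP global permutation p-value (add-one estimator).
#' @slot roiLabels ROI labels in atlas order.
#' @slot roiStat observed per-ROI statistics.
#' @slot roiPRaw raw per-ROI p-values.
#' @slot roiPHolm Holm step-down adjusted per-ROI p-values.
#' @slot nullGlobal permutation draws of the global maximum.
#' @slot nullROI matrix (permutations x ROIs) of per-ROI null draws.
#' @slot localMethod \code{"permutation"} or \code{"davies"}.
#' @slot family response family used.
#' @slot nPerm number of permutations.
#' @slot seed seed used for the permutation table (NA if none supplied).
#'
#' @seealso [runLaxKAT()], [roiTable()]
#' @exportClass LaxKATResult
setClass("LaxKATResult",
  representation(
    stat = "LaxKATStat",
    globalP = "numeric",
    roiLabels = "character",
    roiStat = "numeric",
    roiPRaw = "numeric",
    roiPHolm = "numeric",
    nullGlobal = "numeric",
    nullROI = "matrix",
    localMethod = "character",
    family = "character",
    nPerm = "integer",
    seed = "integer"
  )
)

setValidity("LaxKATResult", function(object) {
  msgs <- character()
  q <- length(object@roiLabels)
  if (q > 0L) {
    if (length(object@roiPRaw) != q || length(object@roiPHolm) != q ||
        length(object@roiStat) != q)
      msgs <- c(msgs, "per-ROI slots must have one entry per ROI")
    if (any(object@roiPHolm + 1e-12 < object@roiPRaw))
      msgs <- c(msgs, "Holm-adjusted p-values cannot fall below raw p-values")
  }
  p <- c(object@globalP, object@roiPRaw, object@roiPHolm)
  if (any(p <= 0 | p > 1))
    msgs <- c(msgs, "all p-values must lie in (0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Simulation scenario
#'
#' Full specification of one synthetic power/FWER/FDR experiment: signal
#' ROIs, effect-variance grid, signal shape (random normal effects or a
#' constant effect), response family, replicate count, permutation count
#' and seed.  The base predictor matrix is regenerated from the scenario
#' seed, so a scenario is exactly reproducible.
#'
#' @slot n subjects.
#' @slot p features.
#' @slot atlas [AtlasBasis-class] partition of the p features.
#' @slot signalROIs integer indices (into atlas ROIs) carrying signal.
#' @slot tau2Grid nonnegative effect-variance grid; must include 0.
#' @slot signalShape \code{"normal"} (gamma ~ N(0, tau2)) or
#'   \code{"constant"} (gamma = tau2 on signal ROIs).
#' @slot family \code{"gaussian"} or \code{"bernoulli"}.
#' @slot nReps replicates per grid point.
#' @slot nPerm permutations per test.
#' @slot seed integer seed.
#'
#' @seealso [simScenario()], [runExperiment()]
#' @exportClass SimScenario
setClass("SimScenario",
  representation(
    n = "integer",
    p = "integer",
    atlas = "AtlasBasis",
    signalROIs = "integer",
    tau2Grid = "numeric",
    signalShape = "character",
    family = "character",
    nReps = "integer",
    nPerm = "integer",
    seed = "integer"
  )
)

setValidity("SimScenario", function(object) {
  msgs <- character()
  q <- length(object@atlas@masks)
  if (object@atlas@p != object@p)
    msgs <- c(msgs, "atlas feature count must equal p")
  if (length(object@signalROIs) &&
      (any(object@signalROIs < 1L) || any(object@signalROIs > q)))
    msgs <- c(msgs, "signalROIs must index atlas ROIs")
  if (!any(object@tau2Grid == 0))
    msgs <- c(msgs, "tau2Grid must include 0 (null point)")
  if (any(object@tau2Grid < 0))
    msgs <- c(msgs, "tau2Grid must be nonnegative")
  if (!object@signalShape %in% c("normal", "constant"))
    msgs <- c(msgs, "signalShape must be 'normal' or 'constant'")
  if (!object@family %in% c("gaussian", "bernoulli"))
    msgs <- c(msgs, "family must be 'gaussian' or 'bernoulli'")
  if (object@nReps < 1L || object@nPerm < 1L)
    msgs <- c(msgs, "nReps and nPerm must be positive")
  if (length(msgs)) msgs else TRUE
})
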