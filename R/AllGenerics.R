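#' Number of regions of interest in a basis
#' @param x an [AtlasBasis-class] or [GeneralBasis-class]
#' @return integer count of basis elements (ROIs)
#' @export
setGeneric("nROI", function(x) standardGeneric("nROI"))

#' Number of features covered by an object
#' @param x an object with a feature dimension
#' @return integer feature count p
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' ROI labels
#' @param x an object carrying ROI labels
#' @return character vector of labels
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))

#' ROI feature masks
#' @param x an [AtlasBasis-class]
#' @return named list of 1-based integer index vectors
#' @export
setGeneric("roiMasks", function(x) standardGeneric("roiMasks"))

#' LaxKAT statistic over a kernel subspace
#'
#' Computes the LaxKAT statistic: the maximum over diagonal weight
#' matrices W in the span of the basis elements of the scaled quadratic
#' form r' Z W^2 Z' r / tr(Delta Z W^2 Z').  For an atlas (mutually
#' exclusive supports) the maximum decouples into a maximum of per-ROI
#' statistics; for a general basis it is the largest generalized
#' eigenvalue of a reduced q x q pencil.
#'
#' @param r numeric residual vector (length n).
#' @param Z numeric predictor matrix (n x p).
#' @param delta numeric dispersion weights (length n); all 1 for a
#'   Gaussian response.
#' @param basis an [AtlasBasis-class] or [GeneralBasis-class].
#' @return a [LaxKATStat-class].
#' @examples
#' set.seed(1)
#' Z <- matrix(rnorm(40), 10, 4)
#' atlas <- atlasFromLabels(c("a", "a", "b", "b"))
#' laxkatStatistic(rnorm(10), Z, rep(1, 10), atlas)
#' @export
setGeneric("laxkatStatistic",
  function(r, Z, delta, basis) standardGeneric("laxkatStatistic"))

#' Convert a basis to its general (matrix) form
#' @param x an [AtlasBasis-class]
#' @return a [GeneralBasis-class] whose column k is the 0/1 indicator of
#'   mask k
#' @export
setGeneric("asGeneralBasis", function(x) standardGeneric("asGeneralBasis"))

#' Per-ROI results table
#' @param x a [LaxKATResult-class]
#' @return data.frame with columns roi_label, Q, p_raw, p_holm
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' Global p-value of a test result
#' @param x a [LaxKATResult-class]
#' @return numeric p-value in (0, 1]
#' @export
setGeneric("globalPValue", function(x) standardGeneric("globalPValue"))

#' Observed statistic of a test result
#' @param x a [LaxKATResult-class]
#' @return the [LaxKATStat-class] observed statistic
#' @export
setGeneric("statValue", function(x) standardGeneric("statValue"))

#' Dispersion weights of a null fit
#' @param x a [NullFit-class]
#' @return numeric vector delta
#' @export
setGeneric("dispersionWeights",
  function(x) standardGeneric("dispersionWeights"))
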