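#' Build an atlas basis from per-feature ROI labels
#'
#' Turns a length-p label vector (one ROI label per feature, e.g. per
#' cortical vertex) into an [AtlasBasis-class]: one mask per distinct
#' label, in order of first appearance.  Features carrying the unassigned
#' code enter no mask and are excluded from every downstream test; the
#' count of excluded features is recorded and reported by \code{show()}.
#'
#' @param labels integer or character vector, one label per feature.
#' @param unassigned label marking features outside the parcellation
#'   (default \code{"-1"}).
#' @return an [AtlasBasis-class].
#' @examples
#' atlasFromLabels(c("A", "A", "B", "-1", "B"))
#' @export
atlasFromLabels <- function(labels, unassigned = "-1") {
  labels <- as.character(labels)
  p <- length(labels)
  if (p < 1L) stop("need at least one feature")
  assigned <- labels != as.character(unassigned)
  if (!any(assigned))
    stop("all features are unassigned; no ROI to test")
  lv <- unique(labels[assigned])          # first-appearance order
  masks <- lapply(lv, function(l) which(labels == l))
  names(masks) <- lv
  new("AtlasBasis", p = as.integer(p), masks = masks, labels = lv,
      nUnassigned = as.integer(sum(!assigned)))
}

#' Test whether basis columns have mutually exclusive supports
#'
#' Pure predicate: \code{TRUE} iff the supports (nonzero coordinates) of
#' every pair of basis columns are disjoint, the condition under which the
#' LaxKAT maximization decouples into per-ROI statistics.
#'
#' @param basis a [GeneralBasis-class].
#' @return logical scalar.
#' @examples
#' validateExclusive(generalBasis(cbind(c(1, 1, 0), c(0, 0, 2))))
#' @export
validateExclusive <- function(basis) {
  stopifnot(is(basis, "GeneralBasis"))
  supp <- basis@basis != 0
  all(rowSums(supp) <= 1L)
}

#' Construct a general basis from a matrix of kernel diagonals
#'
#' @param B numeric matrix (features x basis elements); column k is the
#'   diagonal of the k-th basis element.
#' @return a [GeneralBasis-class].
#' @export
generalBasis <- function(B) {
  B <- as.matrix(B)
  storage.mode(B) <- "double"
  new("GeneralBasis", basis = B)
}

#' @describeIn asGeneralBasis indicator columns of the atlas masks
#' @export
setMethod("asGeneralBasis", "AtlasBasis", function(x) {
  B <- matrix(0, x@p, length(x@masks),
              dimnames = list(NULL, x@labels))
  for (k in seq_along(x@masks)) B[x@masks[[k]], k] <- 1
  new("GeneralBasis", basis = B)
})

#' @describeIn nROI ROIs in an atlas
#' @export
setMethod("nROI", "AtlasBasis", function(x) length(x@masks))

#' @describeIn nROI basis elements of a general basis
#' @export
setMethod("nROI", "GeneralBasis", function(x) ncol(x@basis))

#' @describeIn nFeatures features of an atlas
#' @export
setMethod("nFeatures", "AtlasBasis", function(x) x@p)

#' @describeIn nFeatures features of a general basis
#' @export
setMethod("nFeatures", "GeneralBasis", function(x) nrow(x@basis))

#' @describeIn roiLabels atlas ROI labels
#' @export
setMethod("roiLabels", "AtlasBasis", function(x) x@labels)

#' @describeIn roiMasks atlas masks
#' @export
setMethod("roiMasks", "AtlasBasis", function(x) x@masks)

#' @describeIn AtlasBasis-class summary of the parcellation
#' @param object an \code{AtlasBasis}
#' @export
setMethod("show", "AtlasBasis", function(object) {
  cat(sprintf(
    "AtlasBasis: %d ROIs over %d features (%d unassigned, excluded)\n",
    length(object@masks), object@p, object@nUnassigned))
  sz <- lengths(object@masks)
  cat(sprintf("  mask sizes: min %d, median %g, max %d\n",
              min(sz), stats::median(sz), max(sz)))
})

#' @describeIn GeneralBasis-class summary
#' @param object a \code{GeneralBasis}
#' @export
setMethod("show", "GeneralBasis", function(object) {
  cat(sprintf("GeneralBasis: %d basis elements over %d features (%s)\n",
              ncol(object@basis), nrow(object@basis),
              if (validateExclusive(object)) "mutually exclusive supports"
              else "overlapping supports"))
})
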