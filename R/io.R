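## Delimited-text exchange.  TSV is the canonical dialect: UTF-8, "."
## decimal, header row, first column an id.  Feature/subject ids are
## 1-based in files.

#' Read a numeric matrix from TSV
#'
#' Expects a rectangular tab-separated file with a header row and the
#' first column holding row ids (subject or feature ids).  Ragged rows,
#' non-numeric cells and duplicate ids are rejected with the offending
#' location named.
#'
#' @param path file path.
#' @return numeric matrix with rownames = ids, colnames from the header.
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(nf) < 2L) stop("file has no data rows: ", path)
  bad <- which(nf != nf[1L])
  if (length(bad))
    stop("ragged row(s) in ", path, ": line ",
         paste(bad, collapse = ", "), " (expected ", nf[1L], " fields)")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  if (anyNA(num) ) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric cell in ", path, " at row ", bad[1, 1],
           " (id ", ids[bad[1, 1]], "), column ",
           colnames(vals)[bad[1, 2]])
    bad <- which(is.na(num), arr.ind = TRUE)
    stop("missing value in ", path, " at row ", bad[1, 1],
         ", column ", colnames(vals)[bad[1, 2]])
  }
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write a numeric matrix to TSV
#'
#' Inverse of [readMatrixTSV()]: values are written at full double
#' precision so a write/read round trip is exact.
#'
#' @param m numeric matrix with rownames.
#' @param path output path.
#' @param idCol name for the id column.
#' @return invisibly, \code{path}.
#' @export
writeMatrixTSV <- function(m, path, idCol = "id") {
  stopifnot(!is.null(rownames(m)))
  df <- data.frame(rownames(m),
                   apply(m, 2, function(x) sprintf("%.17g", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idCol, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-feature ROI labels from TSV
#'
#' Two-column TSV (feature_id, roi_label) with a header.  Features are
#' ordered by their (integer) feature_id.
#'
#' @param path file path.
#' @param unassigned label marking unparcellated features.
#' @return an [AtlasBasis-class].
#' @export
readRoiLabels <- function(path, unassigned = "-1") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("ROI label file must have two columns (feature_id, roi_label): ",
         path)
  ord <- order(as.numeric(df[[1L]]))
  atlasFromLabels(df[[2L]][ord], unassigned = unassigned)
}

#' Read a general basis matrix from TSV
#'
#' First column feature_id, remaining q columns the diagonals of the
#' basis elements.
#'
#' @param path file path.
#' @return a [GeneralBasis-class].
#' @export
readBasisMatrix <- function(path) {
  m <- readMatrixTSV(path)
  m <- m[order(as.numeric(rownames(m))), , drop = FALSE]
  generalBasis(m)
}

#' Align response, covariates and predictors on shared subject ids
#'
#' Rows are reordered to the intersection of ids, in response order;
#' dropped subjects are reported via \code{message()}.
#'
#' @param response named numeric vector or 1-column matrix with rownames.
#' @param covariates matrix with rownames.
#' @param predictors matrix with rownames.
#' @return list(response, covariates, predictors, ids) with matching rows.
#' @export
alignInputs <- function(response, covariates, predictors) {
  yv <- if (is.matrix(response)) {
    stats::setNames(response[, 1L], rownames(response))
  } else response
  ids <- names(yv)
  keep <- ids[ids %in% rownames(covariates) & ids %in% rownames(predictors)]
  if (!length(keep))
    stop("no subject ids shared by response, covariates and predictors")
  dropped <- length(ids) - length(keep)
  if (dropped > 0 ||
      nrow(covariates) > length(keep) || nrow(predictors) > length(keep))
    message(sprintf(
      "alignInputs: using %d shared subjects (dropped %d from response, %d from covariates, %d from predictors)",
      length(keep), dropped, nrow(covariates) - length(keep),
      nrow(predictors) - length(keep)))
  list(response = yv[keep],
       covariates = covariates[keep, , drop = FALSE],
       predictors = predictors[keep, , drop = FALSE],
       ids = keep)
}

#' Serialize a LaxKAT result to JSON and per-ROI TSV
#'
#' Writes \code{laxkat_result.json} (statistics, p-values, metadata
#' including seed, permutation count, method, software version and a
#' config hash) and \code{laxkat_roi.tsv} (roi_label, Q, p_raw, p_holm).
#'
#' @param result a [LaxKATResult-class].
#' @param dir output directory (created if needed).
#' @param config optional list echoed into the JSON metadata and hashed.
#' @return invisibly, the JSON path.
#' @export
writeResult <- function(result, dir, config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    seed = result@seed, n_perm = result@nPerm, family = result@family,
    local_method = result@localMethod,
    version = as.character(utils::packageVersion("laxkat")),
    config = config, config_hash = .configHash(config))
  obj <- list(
    statistic = result@stat@value,
    argmax_roi = if (length(result@roiLabels))
      result@roiLabels[result@stat@argmax] else NA,
    global_p = result@globalP,
    roi = roiTable(result),
    metadata = meta)
  jpath <- file.path(dir, "laxkat_result.json")
  jsonlite::write_json(obj, jpath, auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.table(roiTable(result), file.path(dir, "laxkat_roi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(jpath)
}

## md5 of the canonical JSON serialization of the config list
.configHash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}
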