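## Writes a complete toy study (response, covariates, predictors, ROI
## labels) as TSV files into dir and returns the paths.
writeToyStudy <- function(dir, n = 40, p = 30, q = 3, seed = 99,
                          family = "gaussian") {
  set.seed(seed)
  ids <- paste0("s", seq_len(n))
  atlas <- rep(paste0("roi", seq_len(q)), each = p / q)
  Z <- matrix(rnorm(n * p, 2.5, 0.3), n, p,
              dimnames = list(ids, paste0("v", seq_len(p))))
  X <- matrix(cbind(rnorm(n, 72, 5), rbinom(n, 1, 0.5)), n, 2,
              dimnames = list(ids, c("age", "sex")))
  y <- if (family == "bernoulli") rbinom(n, 1, 0.5) else rnorm(n)
  ym <- matrix(y, n, 1, dimnames = list(ids, "y"))

  paths <- list(
    response = file.path(dir, "response.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    predictors = file.path(dir, "predictors.tsv"),
    roi = file.path(dir, "roi_labels.tsv"))
  writeMatrixTSV(ym, paths$response, idCol = "id")
  writeMatrixTSV(X, paths$covariates, idCol = "id")
  writeMatrixTSV(Z, paths$predictors, idCol = "id")
  writeLines(c("feature_id\troi_label",
               paste(seq_len(p), atlas, sep = "\t")), paths$roi)
  paths
}
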