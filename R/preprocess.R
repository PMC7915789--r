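#' Residualize morphometric features against age, sex, and brain size
#'
#' Fits, independently for each of the 74 bilateral features, an ordinary
#' least-squares model `value ~ intercept + age + sex + icv` on the fitting
#' set and returns `observed - predicted` for every subject (patients
#' included). The default fits on controls only, so disease-related atrophy
#' cannot contaminate the covariate slopes; `fit_on = "all"` pools both
#' groups. Sex is coded male = 1, female = 0 (any consistent binary coding
#' yields identical residuals).
#'
#' @param features a bilateral [morph_table] (74 features per subject).
#' @param covariates a covariate table covering every subject
#'   (see [read_covariates()]).
#' @param fit_on `"controls"` (default) or `"all"`: the subjects the
#'   regression coefficients are estimated from.
#' @return numeric matrix (subjects x 74) of residuals, with the fitted
#'   coefficient matrix attached as attribute `"coefficients"`
#'   (4 x 74: intercept, age, sex, icv).
#' @export
residualize <- function(features, covariates, fit_on = c("controls", "all")) {
  fit_on <- match.arg(fit_on)
  stopifnot(inherits(features, "morph_table"))
  if (!is_bilateral(features))
    stop("features must be bilaterally averaged first (see bilateral_average)")
  check_subjects_covered(features, covariates)
  Y <- features$values
  cov <- covariates[match(rownames(Y), covariates$subject_id), , drop = FALSE]
  X <- cbind(intercept = 1, age = cov$age,
             sex = as.numeric(cov$sex == "male"), icv = cov$icv)
  fit_idx <- if (fit_on == "controls") which(cov$group == "control")
             else seq_len(nrow(Y))
  if (length(fit_idx) < 5)
    stop("need at least 5 subjects in the fitting set, got ", length(fit_idx))
  Xf <- X[fit_idx, , drop = FALSE]
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    dropped <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("rank-deficient covariate design; collinear covariate(s): ",
         paste(dropped, collapse = ", "))
  }
  beta <- qr.coef(qrX, Y[fit_idx, , drop = FALSE])
  res <- Y - X %*% beta
  attr(res, "coefficients") <- beta
  res
}

#' Z-score residuals against control-group statistics
#'
#' For each feature, `z = (residual - control_mean) / control_SD`, where
#' the mean and the sample (n-1 denominator) standard deviation are
#' computed over the control subjects only. By construction the control
#' group has per-feature mean 0 and SD 1.
#'
#' @param residuals numeric matrix (subjects x features) with subject-id
#'   rownames, e.g. from [residualize()].
#' @param control_ids character vector of control subject ids (must match
#'   rownames of `residuals`).
#' @return numeric matrix of z-scores, same shape as `residuals`.
#' @export
zscore_by_controls <- function(residuals, control_ids) {
  stopifnot(is.matrix(residuals), !is.null(rownames(residuals)))
  ctrl <- match(control_ids, rownames(residuals))
  if (anyNA(ctrl))
    stop("control ids not found: ",
         paste(control_ids[is.na(ctrl)], collapse = ", "))
  if (length(ctrl) < 2) stop("need at least 2 controls")
  R <- residuals[ctrl, , drop = FALSE]
  mu <- colMeans(R)
  sdev <- apply(R, 2, sd)
  if (any(sdev <= 0))
    stop("zero control SD for feature: ",
         paste(colnames(residuals)[sdev <= 0], collapse = ", "))
  z <- sweep(sweep(residuals, 2, mu, "-"), 2, sdev, "/")
  if (any(!is.finite(z))) stop("non-finite z-scores produced")
  z
}

#' Residualize and z-score in one step
#'
#' Convenience wrapper: [residualize()] followed by [zscore_by_controls()]
#' using the control subjects from the covariate table.
#'
#' @inheritParams residualize
#' @return z-score matrix (subjects x 74 nodes).
#' @export
preprocess_morphometry <- function(features, covariates,
                                   fit_on = c("controls", "all")) {
  res <- residualize(features, covariates, fit_on)
  zscore_by_controls(res, covariates$subject_id[covariates$group == "control"])
}

#' Export a z-score table as TSV
#' @param z z-score matrix (subjects x nodes).
#' @param path output path.
#' @export
write_zscore_table <- function(z, path) {
  df <- data.frame(subject_id = rownames(z), z, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
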