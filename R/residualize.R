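#' Regress nuisance covariates out of a measurement matrix
#'
#' Each column of `x` is replaced by its least-squares residual against the
#' covariate design (indicator-coded factors plus an intercept). Residuals are
#' orthogonal to every covariate column; redundant (collinear) covariate
#' columns are dropped with a warning via QR pivoting.
#'
#' @param x numeric matrix or data.frame, one column per measure.
#' @param covariates data.frame of covariates (e.g. sex, acquisition site),
#'   or NULL for intercept-only centering. Factors/characters are expanded to
#'   indicators.
#' @return list with `residuals` (matrix, same shape as `x`) and
#'   `coefficients` (covariate-design coefficients, for applying the same
#'   adjustment to new subjects via [apply_residualization()]).
#' @export
residualize <- function(x, covariates = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  d <- residual_design(covariates, nrow(x))
  qd <- qr(d)
  if (qd$rank < ncol(d)) {
    dropped <- colnames(d)[qd$pivot[(qd$rank + 1):ncol(d)]]
    warning("dropping redundant covariate column(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qd, x)
  beta[is.na(beta)] <- 0
  res <- x - d %*% beta
  structure(list(residuals = res, coefficients = beta,
                 design_columns = colnames(d)),
            class = "bt_residualization")
}

#' Apply a fitted residualization to new subjects
#'
#' @param fit object from [residualize()].
#' @param x measurement matrix for new subjects.
#' @param covariates covariate data.frame for the same subjects.
#' @return residual matrix using the training-estimated coefficients.
#' @export
apply_residualization <- function(fit, x, covariates = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  d <- residual_design(covariates, nrow(x))
  d <- d[, fit$design_columns, drop = FALSE]
  x - d %*% fit$coefficients
}

residual_design <- function(covariates, n) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0) {
    return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates <- as.data.frame(covariates)
  covariates[] <- lapply(covariates, function(col) {
    if (is.character(col)) factor(col) else col
  })
  # xlev-free: model.matrix on the supplied rows; apply_residualization aligns
  # by column name so unseen levels in new data raise an informative error.
  mm <- model.matrix(~ ., data = covariates)
  mm
}
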