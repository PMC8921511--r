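#' @include AllClasses.R bvls.R
#' @importFrom stats lm pf pt quantile rnorm rbinom setNames sd
NULL

#' Ordinary least-squares fit with coefficient and overall inference
#'
#' Fits `y ~ X` by ordinary least squares (via [stats::lm()]) and
#' returns the coefficients, two-sided t-test p-values per coefficient,
#' the coefficient of determination, the overall F-test p-value and the
#' residuals.  This is the inference step of the two-stage procedure:
#' the bounded solver only decides which variables survive, the
#' reported statistics come from this unconstrained refit.
#'
#' @param y numeric response vector.
#' @param X numeric matrix of the selected variables (full column rank),
#'   with column names; may have zero columns for an intercept-only fit.
#' @return A [FitResult-class].
#' @seealso [selectModel()], [fitBounded()]
#' @export
inferOls <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(names(y)) && !is.null(rownames(X))) names(y) <- rownames(X)
  if (ncol(X) == 0L) return(.interceptOnlyFit(y))
  if (is.null(colnames(X))) stop("X must have column names")
  df <- data.frame(.y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste0("`.y` ~ ",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- lm(fml, data = df)
  if (fit$rank < ncol(X) + 1L)
    stop("rank-deficient design in OLS refit; remove collinear variables")
  sm <- summary(fit)
  cf <- sm$coefficients
  nms <- colnames(X)
  rownames(cf) <- gsub("`", "", rownames(cf))
  res <- setNames(stats::residuals(fit),
                  if (is.null(names(y))) as.character(seq_along(y)) else names(y))
  fstat <- sm$fstatistic
  new("FitResult",
      beta0 = unname(cf["(Intercept)", 1L]),
      betas = setNames(cf[nms, 1L], nms),
      pvalues = setNames(cf[nms, 4L], nms),
      r2 = unname(sm$r.squared),
      fitPvalue = unname(pf(fstat[1L], fstat[2L], fstat[3L],
                            lower.tail = FALSE)),
      residuals = res, selected = nms,
      ySd = sd(y), interceptOnly = FALSE)
}

.interceptOnlyFit <- function(y) {
  res <- y - mean(y)
  if (is.null(names(res))) names(res) <- as.character(seq_along(y))
  new("FitResult", beta0 = mean(y),
      betas = setNames(numeric(0), character(0)),
      pvalues = setNames(numeric(0), character(0)),
      r2 = 0, fitPvalue = NA_real_, residuals = res,
      selected = character(0), ySd = sd(y), interceptOnly = TRUE)
}

#' Sign-constrained model selection
#'
#' The selection procedure of the TF regression: iterate
#' (1) a bounded-variable least-squares fit ([fitBounded()]) on the
#' current candidate set, (2) removal of every variable pinned at a zero
#' bound (its sign violates the constraint), (3) an ordinary
#' least-squares refit ([inferOls()]) on the survivors, and (4) backward
#' elimination of the single survivor with the largest p-value when that
#' p-value is `>= alpha` (ties broken by lexicographic variable name).
#' The loop stops when the bounded fit zeroes nothing and every survivor
#' has `p < alpha`; the reported coefficients and p-values are those of
#' the final unconstrained refit (when no constraint is active the two
#' fits coincide).
#'
#' @param y numeric response vector (log2 target expression).
#' @param X numeric matrix of candidate variables (columns named).
#' @param spec a [designSpec()] over the candidates; default constrains
#'   every candidate non-negative.
#' @param alpha per-coefficient significance threshold (0.001 for the TF
#'   model, 0.01 for the combined model).
#' @return A [FitResult-class]; intercept-only (flagged via
#'   `selectedVariables()` empty) when no candidate survives.
#' @examples
#' set.seed(2)
#' X <- matrix(rnorm(300, 4), 100, 3,
#'             dimnames = list(NULL, c("IRF1", "NFKB", "MYC")))
#' y <- -1 + 0.6 * X[, "IRF1"] + 0.8 * X[, "NFKB"] + rnorm(100, 0, 0.5)
#' selectedVariables(selectModel(y, X))
#' @export
selectModel <- function(y, X, spec = designSpec(colnames(X)), alpha = 0.001) {
  X <- as.matrix(X)
  vars <- spec$variables
  repeat {
    if (length(vars) == 0L) return(.interceptOnlyFit(y))
    sub <- designSpec(vars, lower = spec$lower[vars], upper = spec$upper[vars])
    b <- fitBounded(y, X, sub)
    zeroed <- vars[(sub$lower[vars] == 0 | sub$upper[vars] == 0) &
                     b[vars] == 0]
    surv <- setdiff(vars, zeroed)
    if (length(surv) == 0L) return(.interceptOnlyFit(y))
    fit <- inferOls(y, X[, surv, drop = FALSE])
    ps <- pvalues(fit)
    ps[!is.finite(ps)] <- 1   # degenerate inference (e.g. constant y): drop
    worstP <- max(ps)
    if (worstP >= alpha) {
      worst <- sort(names(ps)[ps == worstP])[1L]
      vars <- setdiff(surv, worst)
      next
    }
    if (length(surv) == length(vars)) return(fit)
    vars <- surv
  }
}

#' Predict the response from a fitted model
#'
#' `yhat = beta0 + sum_i beta_i x_i` over the selected variables.
#'
#' @param object a [FitResult-class].
#' @param X numeric matrix (or data.frame) containing at least the
#'   selected variables as named columns; rows are patients.
#' @param ... ignored.
#' @return Named numeric vector of predictions.
#' @export
setMethod("predict", "FitResult", function(object, X, ...) {
  X <- as.matrix(X)
  if (object@interceptOnly)
    return(setNames(rep(object@beta0, nrow(X)), rownames(X)))
  miss <- setdiff(object@selected, colnames(X))
  if (length(miss))
    stop(sprintf("X is missing selected variable(s): %s",
                 paste(miss, collapse = ", ")))
  yhat <- object@beta0 +
    drop(X[, object@selected, drop = FALSE] %*% object@betas[object@selected])
  setNames(yhat, rownames(X))
})

#' Per-patient contributions of the selected variables
#'
#' Translates the regression coefficients into per-patient percentage
#' contributions: for patient i and variable j,
#' `C_ij = beta_j x_ij / sum_k beta_k x_ik * 100`.  The denominator
#' excludes the intercept and includes negative terms, so contributions
#' can exceed 100% or be negative (a negatively acting variable such as
#' BRD4), but they always sum to 100% per patient.  Patients whose
#' denominator is smaller in magnitude than `tol` are flagged undefined
#' and excluded from the per-variable mean/SD summary.
#'
#' @param fit a [FitResult-class] with at least one selected variable.
#' @param X numeric matrix containing the selected variables.
#' @param tol near-zero denominator tolerance; default `1e-9 * ySd(fit)`.
#' @return list with `perPatient` (patients x variables percentage
#'   matrix, flagged patients as NA), `summary` (data.frame of
#'   per-variable mean and SD across non-flagged patients), and
#'   `excluded` (character vector of flagged patient ids).
#' @export
contributions <- function(fit, X, tol = NULL) {
  stopifnot(is(fit, "FitResult"))
  if (fit@interceptOnly || length(fit@selected) == 0L)
    stop("contributions require at least one selected variable")
  X <- as.matrix(X)
  miss <- setdiff(fit@selected, colnames(X))
  if (length(miss))
    stop(sprintf("X is missing selected variable(s): %s",
                 paste(miss, collapse = ", ")))
  if (is.null(tol)) tol <- 1e-9 * fit@ySd
  terms <- sweep(X[, fit@selected, drop = FALSE], 2L,
                 fit@betas[fit@selected], `*`)
  denom <- rowSums(terms)
  flagged <- abs(denom) < tol
  C <- terms / denom * 100
  C[flagged, ] <- NA_real_
  ok <- C[!flagged, , drop = FALSE]
  summ <- data.frame(
    variable = fit@selected,
    mean = if (nrow(ok)) colMeans(ok) else NA_real_,
    sd = if (nrow(ok) > 1L) apply(ok, 2L, sd) else NA_real_,
    row.names = NULL)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  list(perPatient = C, summary = summ, excluded = ids[flagged])
}

#' Variance inflation factors of a design
#'
#' For each variable i, regresses `x_i` on the remaining variables (with
#' intercept) and reports the auxiliary `R_i^2` and
#' `VIF_i = 1 / (1 - R_i^2)`.  A VIF of 1 means the variable is
#' uncorrelated with the rest; values above 4 flag problematic
#' coefficient estimation and above 10 substantial multicollinearity.
#' Perfectly collinear variables are reported with `VIF = Inf`.
#'
#' @param X numeric matrix with at least two named columns.
#' @return data.frame with columns `variable`, `r2Aux`, `vif`,
#'   `flagAbove4`, `flagAbove10`.
#' @examples
#' X <- cbind(a = c(1, -1, 1, -1), b = c(1, 1, -1, -1))
#' vifReport(X)$vif  # 1, 1 for orthogonal predictors
#' @export
vifReport <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("VIF requires at least two variables")
  if (is.null(colnames(X))) stop("X must have column names")
  r2Aux <- vapply(seq_len(ncol(X)), function(i) {
    fit <- lm(X[, i] ~ X[, -i, drop = FALSE])
    summary(fit)$r.squared
  }, numeric(1))
  vif <- ifelse(r2Aux >= 1 - 1e-12, Inf, 1 / (1 - r2Aux))
  data.frame(variable = colnames(X), r2Aux = r2Aux, vif = vif,
             flagAbove4 = vif > 4, flagAbove10 = vif > 10,
             row.names = NULL)
}
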