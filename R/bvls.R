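#' @include AllClasses.R
NULL

#' Design specification for a bounded least-squares fit
#'
#' Per-variable box bounds for [fitBounded()] and [selectModel()].  The
#' default models the sign convention of the TF regression: every
#' coefficient is constrained non-negative except those of the variables
#' named in `allowNegative` (BRD4 in the motivating application) and the
#' intercept, which is always unbounded and need not be listed.
#'
#' @param variables ordered character vector of variable names.
#' @param lower,upper optional named numeric bounds; unspecified
#'   variables default to `lower = 0`, `upper = Inf`.
#' @param allowNegative variables whose lower bound is set to `-Inf`.
#' @param nonPositive variables constrained `<= 0` (lower `-Inf`, upper
#'   0), e.g. an average-miRNA term modeled strictly as a negative
#'   regulator.
#' @return list of class `"designSpec"` with elements `variables`,
#'   `lower`, `upper`.
#' @examples
#' designSpec(c("IRF1", "STAT1", "BRD4"), allowNegative = "BRD4")
#' @export
designSpec <- function(variables, lower = NULL, upper = NULL,
                       allowNegative = character(0),
                       nonPositive = character(0)) {
  stopifnot(is.character(variables), !anyDuplicated(variables))
  lo <- setNames(rep(0, length(variables)), variables)
  hi <- setNames(rep(Inf, length(variables)), variables)
  lo[intersect(allowNegative, variables)] <- -Inf
  lo[intersect(nonPositive, variables)] <- -Inf
  hi[intersect(nonPositive, variables)] <- 0
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo > hi)) stop("lower bounds must not exceed upper bounds")
  structure(list(variables = variables, lower = lo, upper = hi),
            class = "designSpec")
}

# Active-set bounded-variable least squares:
# minimize ||b - A beta||^2 subject to lo <= beta <= hi.
# Variables sit either in the free set (solved by unconstrained LS) or
# exactly at a bound.  Each outer iteration frees the bound variable whose
# KKT multiplier most favors moving into the feasible region; the inner
# loop solves the free-set LS and, if the solution leaves the box, steps
# the longest feasible fraction toward it and fixes the first variable to
# hit its bound.  Terminates when the free solution is interior and no
# bound variable has a descent direction into the box (KKT conditions of
# this convex QP), so the returned solution is the global minimizer.
.bvls <- function(A, b, lo, hi, tol = NULL, maxOuter = NULL) {
  p <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(1, sum(abs(crossprod(A, b))))
  if (is.null(maxOuter)) maxOuter <- 20L * (p + 1L)^2
  beta <- pmin(pmax(0, lo), hi)          # feasible start
  free <- !is.finite(lo) & !is.finite(hi)  # unbounded vars cannot sit at a bound

  solveFree <- function(free, beta) {
    if (!any(free)) return(beta)
    rhs <- b - A[, !free, drop = FALSE] %*% beta[!free]
    qrF <- qr(A[, free, drop = FALSE])
    if (qrF$rank < sum(free))
      stop("rank-deficient design after bound activation; ",
           "remove collinear variables")
    z <- qr.coef(qrF, rhs)
    beta[free] <- z
    beta
  }

  for (outer in seq_len(maxOuter)) {
    # inner loop: restrict the free-set LS solution to the box
    repeat {
      cand <- solveFree(free, beta)
      viol <- free & (cand < lo - 1e-12 | cand > hi + 1e-12)
      if (!any(viol)) { beta <- cand; break }
      # largest feasible step from beta toward cand
      d <- cand - beta
      alpha <- rep(1, p)
      low <- viol & d < 0
      upp <- viol & d > 0
      alpha[low] <- (lo[low] - beta[low]) / d[low]
      alpha[upp] <- (hi[upp] - beta[upp]) / d[upp]
      aStar <- max(0, min(alpha[viol]))
      beta <- beta + aStar * d
      hit <- which(viol & alpha <= aStar + 1e-15)
      beta[hit] <- ifelse(d[hit] < 0, lo[hit], hi[hit])
      free[hit] <- FALSE
      if (!any(free)) break
    }
    # KKT check on bound variables
    g <- drop(crossprod(A, b - A %*% beta))   # -1/2 gradient of SSE
    atLo <- !free & is.finite(lo) & abs(beta - lo) <= 1e-12 * (1 + abs(lo))
    atHi <- !free & is.finite(hi) & abs(beta - hi) <= 1e-12 * (1 + abs(hi))
    wantFree <- (atLo & g > tol) | (atHi & !atLo & g < -tol)
    if (!any(wantFree)) break
    free[which.max(abs(g) * wantFree)] <- TRUE
  }
  # snap to exact bound values
  snapLo <- is.finite(lo) & abs(beta - lo) <= 1e-9 * (1 + abs(lo))
  snapHi <- is.finite(hi) & abs(beta - hi) <= 1e-9 * (1 + abs(hi))
  beta[snapLo] <- lo[snapLo]
  beta[snapHi] <- hi[snapHi]
  beta
}

#' Bounded-variable least squares fit
#'
#' Minimizes `||y - beta0 - X beta||^2` subject to the per-variable box
#' bounds of `spec`; the intercept is always unbounded.  Coefficients at
#' an active bound are returned exactly at the bound value.  Used inside
#' [selectModel()] to zero out sign-violating variables; statistical
#' inference comes from the ordinary least-squares refit on the
#' surviving set (see [inferOls()]).
#'
#' @param y numeric response vector.
#' @param X numeric matrix with columns named as in `spec$variables`
#'   (extra columns are ignored); `nrow(X) == length(y)` and more rows
#'   than fitted coefficients are required.
#' @param spec a [designSpec()].
#' @return Named coefficient vector `c("(Intercept)", spec$variables)`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- 2 - 0.5 * x + rnorm(30)  # negative true slope
#' fitBounded(y, cbind(x = x), designSpec("x"))  # slope pinned at 0
#' @export
fitBounded <- function(y, X, spec) {
  stopifnot(inherits(spec, "designSpec"))
  X <- as.matrix(X)
  vars <- spec$variables
  if (!all(vars %in% colnames(X)))
    stop(sprintf("design matrix is missing variable(s): %s",
                 paste(setdiff(vars, colnames(X)), collapse = ", ")))
  X <- X[, vars, drop = FALSE]
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (nrow(X) <= ncol(X) + 1L)
    stop("more observations than coefficients are required")
  A <- cbind(`(Intercept)` = 1, X)
  lo <- c(-Inf, spec$lower[vars])
  hi <- c(Inf, spec$upper[vars])
  beta <- .bvls(A, y, lo, hi)
  setNames(beta, colnames(A))
}
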