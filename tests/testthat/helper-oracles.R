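# Independent oracles and small fixture builders used across the suite.

# Toy ExpressionMatrix from a named value list.
toyExpr <- function(values, unit = "synthetic") {
  ExpressionMatrix(values, unit)
}

# Grid-search oracle for 2-predictor box-constrained least squares with a
# free intercept.  The intercept is profiled out exactly (for fixed slopes
# the optimal intercept is mean(y - X beta)), leaving a convex SSE over
# (b1, b2).  Convexity makes coarse-to-fine refinement exact to the final
# step size: the coarse minimizer is within one coarse step of the true
# minimizer, so the fine window around it contains the global optimum.
gridBvls2 <- function(y, X, lo = c(0, 0), hi = c(5, 5), step = 1e-3) {
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  G <- crossprod(Xc)
  v <- crossprod(Xc, yc)
  cc <- sum(yc^2)
  refine <- function(lo1, hi1, lo2, hi2, st) {
    gr <- expand.grid(b1 = seq(lo1, hi1, by = st),
                      b2 = seq(lo2, hi2, by = st))
    sse <- cc - 2 * (gr$b1 * v[1] + gr$b2 * v[2]) +
      gr$b1^2 * G[1, 1] + 2 * gr$b1 * gr$b2 * G[1, 2] + gr$b2^2 * G[2, 2]
    gr[which.min(sse), ]
  }
  coarse <- refine(lo[1], hi[1], lo[2], hi[2], 0.05)
  fine <- refine(max(lo[1], coarse$b1 - 0.06), min(hi[1], coarse$b1 + 0.06),
                 max(lo[2], coarse$b2 - 0.06), min(hi[2], coarse$b2 + 0.06),
                 step)
  b <- c(fine$b1, fine$b2)
  c(mean(y) - sum(colMeans(X) * b), b)
}

# Exhaustive-enumeration two-sided Mann-Whitney p-value: distribution of
# the U statistic over all choose(n1+n2, n1) group assignments of the
# pooled values.
enumMannWhitneyP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- uStat(x, y)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) uStat(pooled[i], pooled[-i]))
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Exhaustive-permutation two-sided Pearson p-value (all n! orderings of y).
permPearsonP <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  obs <- abs(cor(x, y))
  pm <- perms(seq_along(y))
  rs <- apply(pm, 1, function(i) abs(cor(x, y[i])))
  mean(rs >= obs - 1e-12)
}

# Tiny aligned cohort with hand-set mutation events, used by the
# discovery and attribution tests.
toyMutationCohort <- function() {
  ids <- sprintf("P%02d", 1:10)
  ev <- matrix(0L, 3, 10, dimnames = list(c("g1", "g2", "g3"), ids))
  ev["g1", 1:4] <- 1L
  ev["g2", c(1, 5)] <- 1L
  MutationEventTable(ev)
}
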