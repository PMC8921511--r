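olsCoef <- function(y, X) {
  qr.coef(qr(cbind(1, X)), y)
}

test_that("fitBounded equals closed-form OLS when bounds are inactive", {
  set.seed(101)
  for (rep in 1:10) {
    X <- matrix(rnorm(90, 4), 30, 3,
                dimnames = list(NULL, c("A", "B", "C")))
    y <- 1 + 2 * X[, 1] + 0.5 * X[, 2] + 3 * X[, 3] + rnorm(30, 0, 0.3)
    b <- fitBounded(y, X, designSpec(c("A", "B", "C")))
    expect_lt(max(abs(b - olsCoef(y, X))), 1e-8)
  }
})

test_that("a negative OLS slope is pinned exactly at the zero bound", {
  set.seed(102)
  x <- rnorm(30, 4)
  y <- 5 - 2 * x + rnorm(30, 0, 0.5)
  b <- fitBounded(y, cbind(x = x), designSpec("x"))
  expect_identical(unname(b["x"]), 0)
  expect_equal(unname(b["(Intercept)"]), mean(y))
})

test_that("fitBounded matches the grid-search oracle on 2-predictor problems", {
  set.seed(103)
  for (rep in 1:12) {
    X <- matrix(rnorm(60, 3, 1.5), 30, 2, dimnames = list(NULL, c("u", "v")))
    trueB <- runif(2, -1, 3)
    y <- 0.5 + X %*% trueB + rnorm(30, 0, 0.8)
    b <- fitBounded(drop(y), X,
                    designSpec(c("u", "v"), upper = c(u = 5, v = 5)))
    g <- gridBvls2(drop(y), X)
    expect_lt(max(abs(b[c("u", "v")] - g[2:3])), 2e-3)
  }
})

test_that("fitBounded objective beats every feasible grid point", {
  set.seed(104)
  X <- matrix(rnorm(40, 2), 20, 2, dimnames = list(NULL, c("u", "v")))
  y <- drop(1 - 0.7 * X[, 1] + 0.4 * X[, 2] + rnorm(20, 0, 0.5))
  b <- fitBounded(y, X, designSpec(c("u", "v")))
  sse <- function(b0, b1, b2) sum((y - b0 - X %*% c(b1, b2))^2)
  best <- sse(b[1], b[2], b[3])
  grid <- expand.grid(b1 = seq(0, 2, 0.1), b2 = seq(0, 2, 0.1))
  for (i in seq_len(nrow(grid))) {
    b0 <- mean(y - X %*% as.numeric(grid[i, ]))
    expect_gte(sse(b0, grid$b1[i], grid$b2[i]), best - 1e-10)
  }
})

test_that("mixed bounds: non-positive and unbounded variables are honored", {
  set.seed(105)
  X <- matrix(rnorm(120, 3), 40, 3, dimnames = list(NULL, c("tf", "brd", "mir")))
  y <- drop(2 + 1.5 * X[, "tf"] - 0.8 * X[, "brd"] - 0.6 * X[, "mir"] +
              rnorm(40, 0, 0.4))
  sp <- designSpec(c("tf", "brd", "mir"), allowNegative = "brd",
                   nonPositive = "mir")
  b <- fitBounded(y, X, sp)
  expect_lt(max(abs(b - olsCoef(y, X))), 1e-8)  # all bounds inactive
  # force the non-positive bound active: positive true effect on mir
  y2 <- drop(2 + 1.5 * X[, "tf"] + 0.9 * X[, "mir"] + rnorm(40, 0, 0.3))
  b2 <- fitBounded(y2, X, sp)
  expect_identical(unname(b2["mir"]), 0)
})

test_that("rank-deficient free designs raise a diagnostic error", {
  X <- cbind(a = rnorm(20), b = 0)
  X <- cbind(X, c = X[, "a"] * 2)
  sp <- designSpec(c("a", "c"), allowNegative = c("a", "c"))
  expect_error(fitBounded(rnorm(20), X, sp), "rank-deficient")
})

test_that("inferOls reproduces exact fits and reports inference", {
  # single predictor y = 2x + 1 on x = 0,1,2: exact coefficients
  fit <- suppressWarnings(inferOls(c(1, 3, 5), cbind(x = c(0, 1, 2))))
  expect_equal(unname(coef(fit)), c(1, 2), tolerance = 1e-12)
  expect_equal(r2(fit), 1)
  # noiseless multiple regression: R^2 = 1, residuals 0
  set.seed(106)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(2 + X %*% c(1, -1, 0.5))
  fit2 <- suppressWarnings(inferOls(y, X))
  expect_equal(r2(fit2), 1)
  expect_lt(max(abs(residuals(fit2))), 1e-10)
  expect_error(inferOls(y, cbind(X, d = X[, "a"])), "rank-deficient")
})

test_that("coefficient p-values are uniform under the null", {
  set.seed(107)
  reps <- 400
  ps <- replicate(reps, {
    X <- cbind(x = rnorm(60))
    pvalues(inferOls(rnorm(60), X))["x"]
  })
  frac <- mean(ps < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 1e-3)
})

test_that("selectModel recovers a planted active set and drops noise", {
  set.seed(108)
  sim <- simulateCohort(simulationConfig(nPatients = 1000, noiseSigma = 1,
                                         nEffectGenes = 0, nEffectMirnas = 0,
                                         seed = 108))
  sets <- selectUniqueTargets(sim$truth@regulons,
                              rownames(sim$truth@activities),
                              expressed = featureIDs(mrna(sim$bundle)))
  act <- computeActivity(mrna(sim$bundle), sets)
  fit <- selectModel(targetExpression(sim$bundle), t(act),
                     designSpec(rownames(act), allowNegative = "BRD4"))
  expect_setequal(selectedVariables(fit), c("IRF1", "STAT1", "NFKB"))
  truth <- sim$truth@config$trueBeta
  sm <- summary(lm(targetExpression(sim$bundle) ~
                     t(act)[, selectedVariables(fit)]))
  se <- sm$coefficients[-1, "Std. Error"]
  names(se) <- selectedVariables(fit)
  for (tf in selectedVariables(fit))
    expect_lt(abs(coef(fit)[tf] - truth[tf]), 3 * se[tf])
})

test_that("all-noise candidates give an intercept-only fit", {
  set.seed(109)
  X <- matrix(rnorm(500, 4), 100, 5,
              dimnames = list(NULL, paste0("N", 1:5)))
  y <- rnorm(100, 2)
  fit <- selectModel(y, X, designSpec(colnames(X)))
  expect_length(selectedVariables(fit), 0)
  expect_equal(coef(fit)[["(Intercept)"]], mean(y))
})

test_that("selectModel is invariant to candidate ordering", {
  set.seed(110)
  X <- matrix(rnorm(400, 4), 100, 4,
              dimnames = list(NULL, c("A", "B", "C", "D")))
  y <- drop(1 + 0.8 * X[, "B"] + rnorm(100, 0, 0.5))
  f1 <- selectModel(y, X, designSpec(c("A", "B", "C", "D")))
  f2 <- selectModel(y, X[, 4:1], designSpec(c("D", "C", "B", "A")))
  expect_setequal(selectedVariables(f1), selectedVariables(f2))
  expect_equal(coef(f1)[selectedVariables(f1)],
               coef(f2)[selectedVariables(f1)])
})

test_that("predict reproduces training fits and flags missing columns", {
  set.seed(111)
  X <- matrix(rnorm(90, 4), 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(0.5 + X %*% c(1, 0.5, 2) + rnorm(30, 0, 0.2))
  fit <- inferOls(y, X)
  expect_equal(unname(predict(fit, X)), unname(y - residuals(fit)),
               tolerance = 1e-10)
  # all-zero design predicts the intercept
  expect_equal(unname(predict(fit, matrix(0, 2, 3,
                                          dimnames = list(NULL, c("a", "b", "c"))))),
               rep(fit@beta0, 2))
  expect_error(predict(fit, X[, 1:2]), "missing selected variable")
})

test_that("held-out RMSE approaches the generating noise level", {
  cfTrain <- simulationConfig(nPatients = 1000, seed = 112,
                              nEffectGenes = 0, nEffectMirnas = 0)
  cfTest <- simulationConfig(nPatients = 1000, seed = 113,
                             nEffectGenes = 0, nEffectMirnas = 0)
  fitOn <- function(sim) {
    sets <- selectUniqueTargets(sim$truth@regulons,
                                rownames(sim$truth@activities),
                                expressed = featureIDs(mrna(sim$bundle)))
    computeActivity(mrna(sim$bundle), sets)
  }
  simTr <- simulateCohort(cfTrain); simTe <- simulateCohort(cfTest)
  actTr <- fitOn(simTr); actTe <- fitOn(simTe)
  fit <- selectModel(targetExpression(simTr$bundle), t(actTr),
                     designSpec(rownames(actTr), allowNegative = "BRD4"))
  rmse <- sqrt(mean((targetExpression(simTe$bundle) -
                       predict(fit, t(actTe)))^2))
  expect_lt(abs(rmse - 0.5), 0.1 * 0.5)
})
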