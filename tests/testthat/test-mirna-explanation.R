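test_that("the Pearson screen keeps negative correlates only", {
  ids <- sprintf("P%02d", 1:30)
  set.seed(150)
  y <- setNames(rnorm(30, 4), ids)
  m <- rbind(anti = max(y) - y,       # r = -1
             copy = y,                # r = +1, must be rejected
             flat = rep(2, 30),       # zero variance, skipped
             noise = pmax(rnorm(30, 2), 0))
  colnames(m) <- ids
  res <- suppressMessages(
    discoverCriticalMirnas(y, toyExpr(m), subset = ids))
  expect_identical(res$mirna, "anti")
  expect_equal(res$r, -1, tolerance = 1e-12)
  expect_identical(attr(res, "skipped"), "flat")
  expect_error(discoverCriticalMirnas(y[1:2], toyExpr(m[, 1:2]),
                                      subset = ids[1:2]), "at least 3")
})

test_that("screen p-values equal cor.test and match permutation p on tiny n", {
  set.seed(151)
  ids <- sprintf("P%d", 1:8)
  y <- setNames(rnorm(8, 4), ids)
  m <- matrix(pmax(rnorm(3 * 8, 2), 0), 3, 8,
              dimnames = list(paste0("mir", 1:3), ids))
  res <- discoverCriticalMirnas(y, toyExpr(m), subset = ids, pMax = 1.01)
  for (i in seq_len(nrow(res))) {
    ct <- cor.test(m[res$mirna[i], ], y)
    expect_equal(res$p[i], ct$p.value, tolerance = 1e-12)
    expect_equal(res$r[i], unname(ct$estimate), tolerance = 1e-12)
  }
  # permutation oracle on n = 6: t-reference p within Monte-Carlo error
  ids6 <- ids[1:6]
  x <- m[1, 1:6]; y6 <- y[1:6]
  pPerm <- permPearsonP(x, y6)
  pT <- cor.test(x, y6)$p.value
  expect_lt(abs(pPerm - pT), 0.12)
})

test_that("null miRNAs are selected at about pMax/2", {
  set.seed(152)
  reps <- 40
  frac <- replicate(reps, {
    ids <- sprintf("P%03d", 1:200)
    y <- setNames(rnorm(200, 4), ids)
    m <- matrix(pmax(rnorm(200 * 200, 2), 0), 200, 200,
                dimnames = list(sprintf("mir%03d", 1:200), ids))
    res <- discoverCriticalMirnas(y, toyExpr(m), subset = ids)
    nrow(res) / 200
  })
  expected <- 0.005
  expect_lt(abs(mean(frac) - expected),
            3 * sqrt(expected * (1 - expected) / (reps * 200)))
})

test_that("averageCriticalExpression is the unweighted row mean", {
  m <- matrix(c(2, 4, 1, 3), 2, 2,
              dimnames = list(c("mirA", "mirB"), c("P1", "P2")))
  em <- toyExpr(m)
  expect_equal(averageCriticalExpression(em, c("mirA", "mirB")),
               c(P1 = 3, P2 = 2))
  expect_equal(averageCriticalExpression(em, "mirA"), m["mirA", ])
  expect_error(averageCriticalExpression(em, character(0)), "no critical")
  # permuting patients permutes the output identically
  avg <- averageCriticalExpression(em, c("mirA", "mirB"))
  em2 <- toyExpr(m[, c("P2", "P1")])
  expect_equal(averageCriticalExpression(em2, c("mirA", "mirB")),
               avg[c("P2", "P1")])
})

test_that("quantile bins follow the low .. high convention", {
  q <- assignQuantiles(setNames(1:8, paste0("P", 1:8)))
  expect_equal(as.vector(table(q$quantile)), rep(2, 4))
  expect_identical(as.character(q$quantile[1:2]), rep("low", 2))
  expect_identical(as.character(q$quantile[7:8]), rep("high", 2))
  # values 1..5 put the cuts exactly at 2, 3, 4; a value equal to a cut
  # point falls in the upper bin (low: < q1 ... high: >= q3)
  v <- setNames(1:5, paste0("T", 1:5))
  qq <- assignQuantiles(v)
  expect_equal(attr(qq, "cutPoints"), c(2, 3, 4))
  expect_identical(as.character(qq$quantile),
                   c("low", "lower-midrange", "upper-midrange",
                     "high", "high"))

  expect_error(assignQuantiles(1:3, k = 4), "at least k")
  expect_warning(assignQuantiles(setNames(rep(1, 8), paste0("P", 1:8))),
                 "degenerate")
})

test_that("quantile bins are invariant under monotone transforms", {
  set.seed(153)
  avg <- setNames(runif(40, 1, 6), sprintf("P%02d", 1:40))
  q1 <- assignQuantiles(avg)
  q2 <- assignQuantiles(2^avg)        # strictly increasing transform
  expect_identical(q1$quantile, q2$quantile)
})

test_that("fitMirnaModel recovers an exact linear relationship", {
  ids <- sprintf("P%02d", 1:20)
  avg <- setNames(seq(1, 4, length.out = 20), ids)
  y <- setNames(5 - 2 * avg, ids)
  fit <- suppressWarnings(fitMirnaModel(y, avg))
  expect_equal(unname(coef(fit)), c(5, -2), tolerance = 1e-10)
  expect_equal(r2(fit), 1)
  # independent vectors: slope not significant most of the time
  set.seed(154)
  ps <- replicate(30, {
    y2 <- setNames(rnorm(100, 4), sprintf("Q%03d", 1:100))
    a2 <- setNames(rnorm(100, 2), names(y2))
    pvalues(fitMirnaModel(y2, a2))[["mirna_average"]]
  })
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("low miRNA abundance enriches the underpredicted group", {
  set.seed(155)
  sim <- simulateCohort(simulationConfig(nPatients = 1000, seed = 155))
  res <- suppressMessages(runPipeline(sim$bundle, sim$truth@regulons))
  expect_true(all(sim$truth@effectMirnas %in% res$criticalMirnasAll$mirna))
  under <- samplesWithLabel(res$classification, "underpredicted")
  acc <- samplesWithLabel(res$classification, "accurate")
  lowFrac <- function(ids)
    mean(res$quantiles$quantile[match(ids, res$quantiles$sample)] == "low")
  expect_gt(lowFrac(under), lowFrac(acc))
  mw <- mannWhitney(res$mirnaAverages[under], res$mirnaAverages[acc])
  expect_lt(mw$p, 0.01)
  # miRNA-only model explains less than the TF model
  expect_lt(r2(res$mirnaFit), r2(res$tfFit))
})
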