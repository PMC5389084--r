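test_that("generators are deterministic per seed and differ across seeds", {
  a <- genExample1(50, 20, seed = 1)
  b <- genExample1(50, 20, seed = 1)
  c <- genExample1(50, 20, seed = 2)
  expect_identical(featureMatrix(a), featureMatrix(b))
  expect_identical(phenotype(a), phenotype(b))
  expect_false(identical(featureMatrix(a), featureMatrix(c)))
  # generation restores the caller's RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(genExample1(20, 10, seed = 5)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the first design has the stated moments and a marginally silent
           fourth feature", {
  gp <- genExample1(5000, 10, seed = 3)
  x <- featureMatrix(gp)
  expect_lt(abs(cor(x[, 1], x[, 2]) - 0.5), 0.05)
  expect_lt(max(abs(colMeans(x))), 0.05)
  expect_lt(max(abs(apply(x, 2, sd) - 1)), 0.05)
  # X4 is correlated sqrt(rho) with the others yet uncorrelated with y
  expect_lt(abs(cor(x[, 4], x[, 7]) - sqrt(0.5)), 0.05)
  big <- genExample1(20000, 6, seed = 4)
  expect_lt(abs(cor(featureMatrix(big)[, 4], phenotype(big))), 0.05)
  # noise features are marginally silent too
  expect_lt(abs(cor(featureMatrix(big)[, 6], phenotype(big))), 0.05)
  expect_error(genExample1(50, 3), "p >= 4")
})

test_that("the SNP designs cut latents into (1/4, 1/2, 1/4) genotypes and use
           the stated effects", {
  gp <- genExample2(10000, 500, seed = 5)
  x <- featureMatrix(gp)
  freqs <- table(factor(x[, 1], levels = 0:2)) / nrow(x)
  expect_true(all(abs(freqs - c(0.25, 0.5, 0.25)) < 0.02))
  md <- S4Vectors::metadata(gp)
  expect_identical(md$influential, c(100L, 200L, 300L, 400L, 500L))
  expect_identical(md$additive[4], 0.8)    # position 400
  expect_identical(md$dominant[4], 1.2)
  # y equals the additive/dominant recoding model exactly (recode:
  # additive (2,1,0) -> (1,0,-1); dominant Aa -> 1)
  xi <- x[, md$influential]
  yhat <- drop((xi - 1) %*% md$additive) + drop((xi == 1) %*% md$dominant)
  resid <- phenotype(gp) - yhat
  expect_lt(abs(mean(resid)), 0.05)
  expect_lt(abs(sd(resid) - 1), 0.05)

  gp3 <- genExample3(10000, 1000, seed = 6)
  x3 <- featureMatrix(gp3)
  f3 <- table(factor(x3[, 500], levels = 0:2)) / nrow(x3)
  expect_true(all(abs(f3 - c(0.25, 0.5, 0.25)) < 0.02))
  beta <- S4Vectors::metadata(gp3)$beta
  expect_length(beta, 10)
  expect_true(all(beta >= 2 & beta <= 3))
  # indicator model: E[y | X = 2] - E[y | X = 1] = beta_j on a one-feature
  # reduction
  j <- 100
  others <- setdiff(S4Vectors::metadata(gp3)$influential, j)
  yr <- phenotype(gp3) -
    drop((x3[, others] == 1) %*% beta[-1]) -
    drop((x3[, others] == 2) %*% (2 * beta[-1]))
  expect_lt(abs(mean(yr[x3[, j] == 2]) - mean(yr[x3[, j] == 1]) - beta[1]), 0.1)
  # adjacent latents follow the AR(1) parameter: compare the genotype-scale
  # correlation with an independent Monte-Carlo of the same cut
  set.seed(7)
  u1 <- rnorm(200000); u2 <- 0.2 * u1 + sqrt(1 - 0.04) * rnorm(200000)
  cut <- function(u) 2 * (u > qnorm(0.75)) + (abs(u) <= qnorm(0.75))
  ref <- cor(cut(u1), cut(u2))
  expect_lt(abs(cor(x3[, 500], x3[, 501]) - ref), 0.05)
  expect_error(genExample2(50, 100), "p >= 500")
  expect_error(genExample3(50, 500), "p >= 1000")
})

test_that("fixedThreshold truncates n/log(n)", {
  expect_identical(fixedThreshold(200), 37L)
  expect_identical(fixedThreshold(200, 2), 74L)
})

test_that("evaluateMethod validates input and reports coherent powers", {
  des <- simulationDesign("example1", n = 80, p = 20, seed = 11)
  expect_error(evaluateMethod("dcsis", des, 2), "fixedD")
  expect_error(evaluateMethod("dcsis", des, 0, fixedD = 5), "nReplicates")
  rep <- evaluateMethod("dcsis", des, 5, fixedD = 5, computeMspe = FALSE)
  expect_identical(rep@nReplicates, 5L)
  expect_lte(rep@strictPower, min(rep@individualPower))
  expect_identical(rep@averageThreshold, 5)
  # beidc path: threshold comes from the elimination, MSPE is computed
  desB <- simulationDesign("example1", n = 60, p = 12, seed = 12)
  cfg <- beConfig(nBootstrap = 20L)
  repB <- evaluateMethod("beidc", desB, 2, config = cfg)
  expect_true(repB@averageThreshold >= 1)
  expect_true(is.finite(repB@cvMspe))
  # determinism of the whole evaluation
  repB2 <- evaluateMethod("beidc", desB, 2, config = cfg)
  expect_identical(repB@averageThreshold, repB2@averageThreshold)
  expect_identical(repB@cvMspe, repB2@cvMspe)
})
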