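test_that("dcov2Hat agrees with the literal triple-sum estimator", {
  # frozen value computed with the brute-force oracle
  expect_equal(dcov2Hat(0:3, 0:3), 0.8125, tolerance = 1e-12)

  set.seed(101)
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    x <- switch(sample(3, 1),
                rnorm(n),
                as.numeric(sample(0:2, n, replace = TRUE)),
                rexp(n))
    y <- switch(sample(3, 1),
                rnorm(n),
                as.numeric(sample(0:2, n, replace = TRUE)),
                rcauchy(n))
    expect_equal(dcov2Hat(x, y), bruteDcov2(x, y), tolerance = 1e-10)
  }
})

test_that("dcov2Hat is symmetric, translation-invariant and zero on constants", {
  set.seed(7)
  x <- rnorm(25); y <- rnorm(25)
  expect_identical(dcov2Hat(x, y), dcov2Hat(y, x))
  expect_equal(dcov2Hat(x + 3.7, y - 2), dcov2Hat(x, y), tolerance = 1e-12)
  expect_identical(dcov2Hat(x, rep(1.5, 25)), 0)
  expect_error(dcov2Hat(x, rnorm(10)), "equal length")
  expect_error(dcov2Hat(1, 2), "at least 2")
})

test_that("dcorrHat lies in [0,1], is 1 on itself, 0 on constants, and is
           affine-invariant", {
  set.seed(8)
  y <- rnorm(40)
  expect_equal(dcorrHat(y, y), 1, tolerance = 1e-12)
  expect_identical(dcorrHat(rep(2, 40), y), 0)
  x <- rnorm(40)
  r0 <- dcorrHat(x, y)
  expect_gte(r0, 0); expect_lte(r0, 1)
  expect_equal(dcorrHat(2.5 * x + 1, -0.3 * y + 4), r0, tolerance = 1e-10)
  # small-n agreement with the brute-force oracle on independent inputs
  set.seed(9)
  for (rep in 1:10) {
    x6 <- rnorm(6); y6 <- rnorm(6)
    expect_equal(dcorrHat(x6, y6), bruteDcorr(x6, y6), tolerance = 1e-10)
  }
})

test_that("dcsisRank sorts by score, breaks ties by original index, sinks
           monomorphic features", {
  set.seed(10)
  x <- matrix(rnorm(60), 20, 3)
  x <- cbind(x, x[, 2])            # duplicate of column 2
  x <- cbind(x, rep(1, 20))        # monomorphic
  y <- x[, 2] + rnorm(20, sd = 0.1)
  rk <- dcsisRank(x, y)
  ord <- rankingOrder(rk)
  # duplicated columns (2 and 4) have identical scores and appear adjacently
  # in original-index order
  pos2 <- which(ord == 2); pos4 <- which(ord == 4)
  expect_identical(pos4, pos2 + 1L)
  expect_identical(ord[length(ord)], 5L)          # monomorphic last
  expect_identical(screenScores(rk)[5], 0)
  expect_identical(screenStage(rk), rep(0L, 5))
  # p = 1
  expect_identical(rankingOrder(dcsisRank(x[, 1, drop = FALSE], y)), 1L)
})

test_that("a strong linear signal attains rank 1 in nearly all replicates", {
  wins <- 0L
  for (r in 1:20) {
    set.seed(200 + r)
    x <- matrix(rnorm(200 * 50), 200, 50)
    y <- 5 * x[, 1] + rnorm(200)
    wins <- wins + (rankingOrder(dcsisRank(x, y))[1] == 1L)
  }
  expect_gte(wins / 20, 0.95)
})
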