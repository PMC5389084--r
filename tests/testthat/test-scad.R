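test_that("the SCAD penalty follows its three branches and is continuous at
           the knots", {
  expect_equal(scadPenalty(0.5, lambda = 1), 0.5)                    # lam |b|
  expect_equal(scadPenalty(10, lambda = 1), (3.7 + 1) / 2)           # flat top
  lam <- 0.8; a <- 3.7
  mid <- 2 * lam
  expect_equal(scadPenalty(mid, lam, a),
               -(mid^2 - 2 * a * lam * mid + lam^2) / (2 * (a - 1)))
  eps <- 1e-9
  expect_equal(scadPenalty(lam + eps, lam, a), scadPenalty(lam, lam, a),
               tolerance = 1e-7)
  expect_equal(scadPenalty(a * lam + eps, lam, a), scadPenalty(a * lam, lam, a),
               tolerance = 1e-7)
  b <- seq(0, 5, by = 0.01)
  expect_true(all(diff(scadPenalty(b, lam, a)) >= -1e-12))           # monotone
  expect_error(scadPenalty(1, lambda = 1, alpha = 2), "alpha")
})

test_that("the solver matches OLS as lambda vanishes and zeroes everything at
           lambda_max", {
  set.seed(31)
  x <- matrix(rnorm(100 * 5), 100, 5)
  y <- drop(x %*% c(2, -1, 0.5, 0, 0)) + rnorm(100)
  cfg <- scadConfig(tol = 1e-10, maxIter = 5000L)
  fit <- fitScad(x, y, lambda = 1e-8, config = cfg)
  ols <- unname(coef(stats::lm(y ~ x)))
  expect_equal(unname(coef(fit)), ols, tolerance = 1e-6)
  # full shrinkage at lambda >= max |x_j' y| / n on the standardised design
  xs <- scale(x, scale = apply(x, 2, function(v) sqrt(mean((v - mean(v))^2))))
  lmax <- max(abs(crossprod(xs, y - mean(y)))) / nrow(x)
  fit0 <- fitScad(x, y, lambda = lmax * 1.001)
  expect_identical(fit0@nonzeroIndexSet, integer(0))
  expect_equal(fit0@intercept, mean(y), tolerance = 1e-10)
})

test_that("on orthonormal designs the solver matches per-coordinate grid
           search and stays monotone in objective", {
  n <- 64
  q <- qr.Q(qr(matrix(rnorm(n * 6), n, 6)))
  q <- q - rep(1, n) %*% crossprod(rep(1, n) / n, q)   # centred
  x <- sqrt(n) * qr.Q(qr(q))                           # x' x = n I, centred
  set.seed(32)
  for (rep in 1:5) {
    beta <- c(0.1, 0.5, 1.2, 3, 8, 0) * sample(c(-1, 1), 6, replace = TRUE)
    y <- drop(x %*% beta) + rnorm(n)
    lam <- runif(1, 0.2, 1)
    cfg <- scadConfig(tol = 1e-10, maxIter = 5000L)
    fit <- fitScad(x, y, lambda = lam, config = cfg)
    z <- drop(crossprod(x, y - mean(y))) / n
    sds <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
    oracle <- vapply(z, gridScadArgmin, numeric(1), lambda = lam, alpha = 3.7)
    expect_equal(fit@beta * sds, oracle, tolerance = 1e-4)
    expect_true(all(diff(fit@objective) <= 1e-10))
  }
})

test_that("the objective trace never increases on general designs", {
  set.seed(33)
  for (rep in 1:5) {
    n <- sample(30:80, 1); k <- sample(3:40, 1)
    x <- matrix(rnorm(n * k), n, k)
    y <- rnorm(n)
    fit <- fitScad(x, y, lambda = runif(1, 0.05, 0.5))
    expect_true(all(diff(fit@objective) <= 1e-10))
  }
})

test_that("near-unbiasedness for large coefficients on orthonormal designs", {
  n <- 64
  q <- matrix(rnorm(n * 4), n, 4)
  q <- scale(q, scale = FALSE)
  x <- sqrt(n) * qr.Q(qr(q))
  bias <- numeric(50)
  for (r in 1:50) {
    set.seed(400 + r)
    y <- 10 * x[, 1] + rnorm(n)
    fit <- fitScad(x, y, lambda = 1, config = scadConfig(tol = 1e-9))
    ols <- drop(crossprod(x[, 1], y - mean(y))) / n /
      sqrt(mean((x[, 1] - mean(x[, 1]))^2))
    bias[r] <- fit@beta[1] * sqrt(mean((x[, 1] - mean(x[, 1]))^2)) - ols
  }
  expect_lt(abs(mean(bias)), 0.05)
})

test_that("cross-validated lambda selection is deterministic, recovers a
           strong coefficient, and produces sparse fits when k >> n", {
  set.seed(34)
  x <- matrix(rnorm(200 * 20), 200, 20)
  y <- 3 * x[, 1] + rnorm(200)
  set.seed(35); a <- cvSelectLambda(x, y)
  set.seed(35); b <- cvSelectLambda(x, y)
  expect_identical(a$lambdaSelected, b$lambdaSelected)
  expect_identical(a$fit@beta, b$fit@beta)

  ok <- 0L
  for (r in 1:20) {
    set.seed(500 + r)
    xr <- matrix(rnorm(200 * 20), 200, 20)
    yr <- 3 * xr[, 1] + rnorm(200)
    cv <- cvSelectLambda(xr, yr)
    ok <- ok + (1L %in% cv$fit@nonzeroIndexSet && abs(cv$fit@beta[1] - 3) < 0.3)
  }
  expect_gte(ok / 20, 0.9)

  sparse <- 0L
  for (r in 1:10) {
    set.seed(600 + r)
    xr <- matrix(rnorm(100 * 500), 100, 500)
    yr <- drop(xr[, 1:3] %*% c(3, 3, 3)) + rnorm(100)
    cv <- cvSelectLambda(xr, yr)
    sparse <- sparse + (length(cv$fit@nonzeroIndexSet) <= 25)
  }
  expect_gte(sparse / 10, 0.9)
})

test_that("pure-noise responses give intercept-dominated models with held-out
           error near var(y)", {
  set.seed(36)
  x <- matrix(rnorm(150 * 10), 150, 10)
  y <- rnorm(150)
  cv <- cvSelectLambda(x, y)
  expect_lte(length(cv$fit@nonzeroIndexSet), 3)
  expect_lt(abs(min(cv$cvm, na.rm = TRUE) - var(y)), 0.35)
  # zero-variance predictors are pinned at zero
  x0 <- cbind(x, 2)
  fit <- fitScad(x0, 3 * x0[, 1] + rnorm(150), lambda = 0.1)
  expect_identical(fit@beta[11], 0)
})
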