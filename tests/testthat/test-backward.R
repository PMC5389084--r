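test_that("eliminateStep follows the ceiling rule and always reaches the
           floor", {
  expect_identical(eliminateStep(5000, 0.5), 2500L)
  expect_identical(eliminateStep(3, 0.5), 1L)      # 3 - ceiling(1.5)
  expect_identical(eliminateStep(1, 0.9), 1L)
  expect_identical(eliminateStep(10, 0.01), 9L)    # forced decrease
  for (p in c(2, 17, 500, 5000)) {
    for (dr in c(0.1, 0.25, 0.5, 0.9)) {
      k <- p; steps <- 0L
      while (k > 1) {
        k2 <- eliminateStep(k, dr)
        expect_lt(k2, k)
        k <- k2; steps <- steps + 1L
        expect_lt(steps, 200L)
      }
    }
  }
})

test_that("selectThreshold takes the MSPE argmin, breaks ties towards fewer
           features, and applies the 1-s.e. rule", {
  mkTrace <- function(sizes, m, se) {
    ids <- paste0("f", seq_len(max(sizes)))
    methods::new("EliminationTrace", poolSizes = as.integer(sizes),
                 mspeMean = m, mspeSe = se,
                 pools = lapply(sizes, function(k) ids[seq_len(k)]))
  }
  tr <- mkTrace(c(100, 50, 25, 12), c(5, 3, 1, 2), rep(0.1, 4))
  res <- selectThreshold(tr)
  expect_identical(dHat(res), 25L)
  expect_identical(selectedFeatures(res), paste0("f", 1:25))
  expect_identical(sort(c(selectedFeatures(res), discardedFeatures(res))),
                   sort(paste0("f", 1:100)))
  # exact tie resolves to the smaller size
  tr2 <- mkTrace(c(50, 25, 12), c(2, 1, 1), rep(0.1, 3))
  expect_identical(dHat(selectThreshold(tr2)), 12L)
  # 1-s.e. rule: smallest size within one s.e. (at the minimiser) of the min
  tr3 <- mkTrace(c(40, 20, 10), c(1.0, 1.05, 1.3), c(0.1, 0.1, 0.1))
  res3 <- selectThreshold(tr3)
  expect_identical(dHat(res3), 40L)
  expect_identical(dOneSe(res3), 20L)
})

test_that("bootstrapMspe is reproducible, exact on constant phenotypes, and
           near the noise floor for strong signals", {
  set.seed(41)
  x <- matrix(rnorm(200 * 5), 200, 5)
  y <- drop(x %*% c(4, 3, 2, 0, 0)) + rnorm(200)
  cfg <- beConfig(nBootstrap = 200L, seed = 77L)
  a <- bootstrapMspe(x, y, cfg)
  b <- bootstrapMspe(x, y, cfg)
  expect_identical(a$mspe, b$mspe)
  expect_gte(a$mean, 1.0)
  expect_lte(a$mean, 1.5)
  # enlarging the bootstrap only appends replicates
  small <- bootstrapMspe(x, y, beConfig(nBootstrap = 50L, seed = 77L))
  expect_identical(small$mspe, a$mspe[1:50])
  # constant phenotype: the intercept fit is exact
  cst <- bootstrapMspe(x, rep(2, 200), beConfig(nBootstrap = 20L, seed = 5L))
  expect_equal(cst$mean, 0, tolerance = 1e-20)
  expect_error(bootstrapMspe(x[1:5, ], y[1:5]), "at least 10")
})

test_that("runBeIdc produces a coherent trace and threshold and is fully
           deterministic", {
  set.seed(42)
  x <- matrix(rnorm(60 * 30), 60, 30)
  y <- drop(x[, c(2, 9)] %*% c(4, -4)) + rnorm(60)
  cfg <- beConfig(nBootstrap = 30L, seed = 9L)
  res <- runBeIdc(x, y, config = cfg, schedule = iterationSchedule(c(3, 3), 6))
  tr <- eliminationTrace(res)
  expect_identical(poolSizes(tr)[1], 30L)
  expect_identical(poolSizes(tr)[length(poolSizes(tr))], 1L)
  expect_true(all(diff(poolSizes(tr)) < 0))
  # every pool is a prefix of the frozen ranking
  ranked <- rankedFeatures(screenRanking(res))
  for (i in seq_along(tr@pools))
    expect_identical(tr@pools[[i]], ranked[seq_len(poolSizes(tr)[i])])
  # the selected set is the first d-hat ranked features
  expect_identical(selectedFeatures(res), ranked[seq_len(dHat(res))])
  # minimum of the trace cannot exceed the full-pool entry
  expect_lte(thresholdResult(res)@mspeAtDHat, mspeMean(tr)[1])
  res2 <- runBeIdc(x, y, config = cfg, schedule = iterationSchedule(c(3, 3), 6))
  expect_identical(selectedFeatures(res2), selectedFeatures(res))
  expect_identical(mspeMean(eliminationTrace(res2)), mspeMean(tr))
  # the signal features survive into the selected set
  expect_true(all(c("snp2", "snp9") %in% selectedFeatures(res)))
})

test_that("under a pure-noise design no pool predicts materially better than
           any other and the threshold stays small", {
  set.seed(43)
  x <- matrix(rnorm(100 * 20), 100, 20)
  y <- rnorm(100)
  res <- runBeIdc(x, y, config = beConfig(nBootstrap = 60L, seed = 13L),
                  schedule = iterationSchedule(c(3, 3), 6))
  m <- mspeMean(eliminationTrace(res))
  # larger pools can only add mild overfitting noise: the whole curve stays
  # within a narrow relative band of its minimum, near var(y)
  expect_lte(max(m) - min(m), 0.15 * min(m))
  expect_lt(abs(min(m) - var(y)), 0.35)
  # the minimum sits among the small pools (least room to overfit)
  expect_lte(dHat(res), 10L)
})
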