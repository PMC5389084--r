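test_that("residualize projects exactly, is idempotent, and handles rank
           deficiency as the pseudo-inverse", {
  # projection onto the constant vector
  expect_equal(residualize(matrix(1, 3, 1), matrix(1:3, 3, 1)),
               matrix(c(-1, 0, 1), 3, 1), tolerance = 1e-12)
  set.seed(21)
  sel <- matrix(rnorm(40), 20, 2)
  rem <- matrix(rnorm(60), 20, 3)
  r1 <- residualize(sel, rem)
  expect_equal(residualize(sel, r1), r1, tolerance = 1e-10)   # idempotent
  # a column orthogonal to the projection basis (intercept included) is
  # returned unchanged
  B <- cbind(1, sel)
  v <- rnorm(20)
  v <- v - B %*% solve(crossprod(B), crossprod(B, v))
  expect_equal(residualize(sel, v), v, tolerance = 1e-10)
  # a column inside the span is annihilated
  inspan <- sel %*% c(2, -1) + 3
  expect_equal(residualize(sel, inspan), matrix(0, 20, 1), tolerance = 1e-10)
  # perfectly linked (duplicated) selected columns: same residuals as the
  # independent least-squares fit on the unduplicated block
  dup <- cbind(sel, sel[, 1])
  lmres <- stats::resid(stats::lm(rem ~ sel))
  expect_equal(unname(residualize(dup, rem)), unname(lmres), tolerance = 1e-8)
  expect_error(residualize(sel[, 0], rem), "at least one column")
})

test_that("idcsisRank emits a permutation, is deterministic, and reduces to
           dcsisRank when one block covers everything", {
  set.seed(22)
  x <- matrix(rnorm(50 * 20), 50, 20)
  y <- x[, 3] - x[, 7] + rnorm(50)
  for (sched in list(iterationSchedule(c(3, 3), 6),
                     iterationSchedule(c(3, 3), 100),
                     iterationSchedule(c(2, 5), 9),
                     iterationSchedule(c(3, 3), 20))) {
    rk <- idcsisRank(x, y, sched)
    expect_identical(sort(rankingOrder(rk)), 1:20)
    expect_identical(rankingOrder(idcsisRank(x, y, sched)), rankingOrder(rk))
  }
  # p <= first block: single stage, identical to the marginal ranking
  big <- iterationSchedule(25, 30)
  expect_identical(rankingOrder(idcsisRank(x, y, big)),
                   rankingOrder(dcsisRank(x, y)))
  # stage bookkeeping: first block stage 1, final sweep stage follows blocks
  rk <- idcsisRank(x, y, iterationSchedule(c(3, 3), 6))
  st <- screenStage(rk)[rankingOrder(rk)]
  expect_identical(st[1:6], rep(1:2, each = 3L))
  expect_true(all(st[7:20] == 3L))
})

test_that("one-at-a-time iterative ranking matches an independent greedy
           enumeration", {
  set.seed(23)
  n <- 30
  x1 <- rnorm(n)
  x <- cbind(x1, x1 + 0.1 * rnorm(n), rnorm(n))
  colnames(x) <- NULL
  y <- x[, 1] - x[, 2]
  rk <- idcsisRank(x, y, iterationSchedule(c(1, 1), 2))
  oracle <- greedyIterativeOrder(x, y)
  expect_identical(rankingOrder(rk), as.integer(oracle))
  # the jointly-important pair outranks pure noise
  expect_setequal(rankingOrder(rk)[1:2], 1:2)
})

test_that("a marginally silent joint feature is recovered by the iterative
           screen", {
  found <- 0L
  for (r in 1:10) {
    gp <- genExample1(200, 100, seed = 3000 + r)
    rk <- idcsisRank(gp, schedule = iterationSchedule(c(3, 3), 6))
    found <- found + (4L %in% rankingOrder(rk)[1:6])
  }
  expect_gte(found / 10, 0.9)
})
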