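#' SCAD penalty function
#'
#' The smoothly clipped absolute deviation penalty, a quadratic spline with
#' knots at \eqn{\lambda} and \eqn{\alpha\lambda}:
#' \deqn{p_\lambda(t) = \lambda t \;\; (t \le \lambda);\quad
#'  -\frac{t^2 - 2\alpha\lambda t + \lambda^2}{2(\alpha-1)}
#'   \;\; (\lambda < t \le \alpha\lambda);\quad
#'  \frac{(\alpha+1)\lambda^2}{2} \;\; (t > \alpha\lambda),}
#' for \eqn{t = |\beta|}. Singular at the origin (sparsity), continuous, and
#' constant beyond \eqn{\alpha\lambda} (near-unbiasedness for large effects).
#'
#' @param betaAbs non-negative numeric vector of coefficient magnitudes.
#' @param lambda positive penalty level.
#' @param alpha shape parameter, must exceed 2 (3.7 by convention).
#' @return Numeric vector of penalty values.
#' @examples
#' scadPenalty(c(0.5, 10), lambda = 1)  # first and third branch
#' @export
scadPenalty <- function(betaAbs, lambda, alpha = 3.7) {
  if (alpha <= 2) stop("alpha must exceed 2")
  if (lambda <= 0) stop("lambda must be positive")
  if (any(betaAbs < 0)) stop("betaAbs must be non-negative")
  vapply(betaAbs, cpp_scad_penalty, numeric(1), lambda = lambda, alpha = alpha)
}

makeScadFit <- function(beta, intercept, lambda, converged,
                        objective = numeric()) {
  nz <- which(beta != 0)
  methods::new("ScadFit", intercept = as.numeric(intercept),
               beta = as.numeric(beta), lambdaSelected = as.numeric(lambda),
               nonzeroIndexSet = as.integer(nz),
               converged = as.logical(converged),
               objective = as.numeric(objective))
}

#' Fit a SCAD-penalised least-squares regression at a fixed lambda
#'
#' Minimises \eqn{(2n)^{-1}\|y - \beta_0 - X\beta\|^2 + \sum_j
#' p_\lambda(|\beta_j|)} (the penalised least-squares criterion scaled by
#' \eqn{1/n}) by cyclic coordinate descent on the internally standardised
#' design; the intercept is unpenalised and coefficients are returned on the
#' original scale. Each coordinate update applies the exact closed-form
#' univariate SCAD solution, so the recorded objective trace is non-increasing
#' across sweeps. Zero-variance columns are pinned at 0.
#'
#' @param x n-by-k numeric design matrix.
#' @param y numeric response of length n.
#' @param lambda positive penalty level.
#' @param config a [ScadConfig-class] (alpha, sweep budget, tolerance).
#' @return A [ScadFit-class]; `@objective` holds the per-sweep trace and
#'   `@converged` is FALSE (with a warning) when the sweep budget ran out.
#' @examples
#' x <- matrix(rnorm(200), 50, 4)
#' y <- 2 * x[, 1] + rnorm(50)
#' coef(fitScad(x, y, lambda = 0.1))
#' @export
fitScad <- function(x, y, lambda, config = scadConfig()) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 observations")
  if (ncol(x) < 1) stop("need at least 1 predictor")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (lambda <= 0) stop("lambda must be positive")
  fit <- cpp_scad_fit(x, as.numeric(y), lambda, config@alpha, config@tol,
                      config@maxIter, NULL)
  if (!fit$converged)
    warning("SCAD coordinate descent did not converge within maxIter sweeps; ",
            "returning the best iterate")
  makeScadFit(fit$beta, fit$intercept, lambda, fit$converged, fit$objective)
}

# Internal: lambda grid of the standardised problem, glmnet-style.
autoLambdaGrid <- function(x, y, config) {
  if (length(config@lambdaGrid)) return(sort(config@lambdaGrid, decreasing = TRUE))
  NULL  # delegated to the C++ path (lambda_max down to lambdaMinRatio * max)
}

#' Cross-validated lambda selection for SCAD regression
#'
#' K-fold cross-validation of the warm-started SCAD path over a log-spaced
#' lambda grid (from the smallest all-zero lambda down to
#' `lambdaMinRatio` times it), selecting the lambda minimising the held-out
#' squared error and refitting on all data. Folds are drawn from the current
#' RNG stream, so results are deterministic given a prior `set.seed()` (or an
#' explicit `foldid`).
#'
#' @inheritParams fitScad
#' @param foldid optional integer vector (1..cvFolds) assigning rows to folds.
#' @return List with `lambdaSelected`, `fit` (a [ScadFit-class]), `lambda`
#'   (the grid) and `cvm` (mean held-out squared error per grid point).
#' @examples
#' x <- matrix(rnorm(500), 100, 5)
#' y <- 3 * x[, 1] + rnorm(100)
#' set.seed(1)
#' cvSelectLambda(x, y)$lambdaSelected
#' @export
cvSelectLambda <- function(x, y, config = scadConfig(), foldid = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (n < config@cvFolds) stop("need at least cvFolds observations")
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (is.null(foldid)) foldid <- sample(rep_len(seq_len(config@cvFolds), n))
  grid <- autoLambdaGrid(x, y, config)
  dfMax <- if (is.na(config@dfMax)) n else as.integer(config@dfMax)
  cv <- cpp_scad_cv(x, as.numeric(y), seq_len(n), as.integer(foldid), grid,
                    config@nLambda, config@lambdaMinRatio, config@alpha,
                    config@tol, config@maxIter, dfMax)
  fit <- makeScadFit(cv$beta, cv$intercept, cv$lambda_selected, cv$converged)
  list(lambdaSelected = cv$lambda_selected, fit = fit,
       lambda = as.numeric(cv$lambda), cvm = as.numeric(cv$cvm))
}

# Internal engine shared by bootstrapMspe and the evaluation harness: CV fit
# on rows `trainRows` with the given fold assignment, then MSPE on testRows.
scadCvPredictMspe <- function(x, y, trainRows, foldid, testRows, config,
                              nLambdaCap = NULL) {
  nl <- config@nLambda
  if (!is.null(nLambdaCap)) nl <- min(nl, nLambdaCap)
  grid <- if (length(config@lambdaGrid))
    sort(config@lambdaGrid, decreasing = TRUE) else NULL
  # saturation is reckoned in distinct observations: duplicated bootstrap
  # rows add weight, not degrees of freedom
  dfMax <- if (is.na(config@dfMax)) length(unique(trainRows))
           else as.integer(config@dfMax)
  cv <- cpp_scad_cv(x, y, as.integer(trainRows), as.integer(foldid), grid, nl,
                    config@lambdaMinRatio, config@alpha, config@tol,
                    config@maxIter, dfMax, 8L, as.integer(testRows))
  mean((y[testRows] - cv$test_pred)^2)
}
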