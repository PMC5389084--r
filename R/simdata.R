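#' Fixed screening thresholds of the form `m * trunc(n / log(n))`
#'
#' The conventional fixed model sizes used by sure-independence screening:
#' `multiplier * trunc(n / log(n))` with the natural logarithm (n = 200 gives
#' 37 and, with multiplier 2, 74).
#'
#' @param n sample size.
#' @param multiplier integral multiplier (1, 2 or 3 in common use).
#' @return Integer threshold.
#' @export
fixedThreshold <- function(n, multiplier = 1L) {
  as.integer(multiplier * floor(n / log(n)))
}

#' Construct a SimulationDesign
#'
#' Parameterises one of the three synthetic validation designs. Defaults
#' reproduce the study conditions: n = 200 throughout; p = 5000 for designs 1
#' and 2, p = 2000 for design 3; unit Gaussian noise.
#'
#' @param name `"example1"`, `"example2"` or `"example3"`.
#' @param n,p sample and feature counts (p may be reduced for desk-scale runs).
#' @param seed base seed.
#' @param rho correlation parameter (design 1 only; 0.5 by default).
#' @param noiseSd noise standard deviation.
#' @return A [SimulationDesign-class].
#' @export
simulationDesign <- function(name = c("example1", "example2", "example3"),
                             n = 200L, p = NULL, seed = 1L, rho = NULL,
                             noiseSd = 1) {
  name <- match.arg(name)
  if (is.null(p)) p <- switch(name, example1 = 5000L, example2 = 5000L,
                              example3 = 2000L)
  inf <- switch(name,
    example1 = 1:4,
    example2 = c(100L, 200L, 300L, 400L, 500L),
    example3 = seq(100L, 1000L, by = 100L))
  coefs <- switch(name,
    example1 = list(beta = c(5, 5, 5, NA)),  # the 4th is -15*sqrt(rho)
    example2 = list(additive = c(1.2, 1.2, 1.2, 0.8, 1.0),
                    dominant = c(0.8, 0.4, 0.8, 1.2, 1.2)),
    example3 = list(betaRange = c(2, 3)))
  corr <- switch(name,
    example1 = if (is.null(rho)) 0.5 else rho,
    example2 = 0.1,
    example3 = 0.2)
  methods::new("SimulationDesign", name = name, n = as.integer(n),
               p = as.integer(p), influentialIndices = as.integer(inf),
               coefficients = coefs, correlation = corr,
               noiseSd = noiseSd, seed = as.integer(seed))
}

# Cut a latent standard-normal matrix into genotype codes at +/- the third
# quartile c = qnorm(0.75): u > c -> 2 (AA), |u| <= c -> 1 (Aa), u < -c -> 0
# (aa), giving genotype frequencies (1/4, 1/2, 1/4).
cutGenotypes <- function(u) {
  cc <- qnorm(0.75)
  2 * (u > cc) + 1 * (u <= cc & u >= -cc)
}

#' Generate the first validation design: continuous features, a marginally
#' silent influential feature
#'
#' Features are jointly Gaussian with unit variance: all pairs share
#' correlation `rho` except the fourth feature, which is the common factor
#' itself and so has correlation `sqrt(rho)` with every other feature. The
#' phenotype is \deqn{y = 5X_1 + 5X_2 + 5X_3 - 15\sqrt{\rho}X_4 + \epsilon,
#' \quad \epsilon \sim N(0, 1),} which makes `cov(X_4, y) = 0` exactly — the
#' fourth feature is jointly important but marginally independent of the
#' phenotype — and leaves every noise feature independent of y.
#'
#' @param n,p dimensions (p >= 4).
#' @param rho correlation parameter (0.5 by default).
#' @param seed generator seed.
#' @param noiseSd noise standard deviation.
#' @return A [GenoPheno-class]; `metadata()` records the influential indices
#'   and coefficients.
#' @examples
#' gp <- genExample1(100, 50, seed = 1)
#' cor(featureMatrix(gp)[, 1], featureMatrix(gp)[, 2])
#' @export
genExample1 <- function(n = 200L, p = 5000L, rho = 0.5, seed = 1L,
                        noiseSd = 1) {
  if (p < 4) stop("example1 needs p >= 4")
  dat <- withSeed(seed, {
    g <- rnorm(n)
    x <- sqrt(rho) * g + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    x[, 4] <- g
    eps <- rnorm(n)
    list(x = x, eps = eps)
  })
  beta <- c(5, 5, 5, -15 * sqrt(rho))
  y <- drop(dat$x[, 1:4] %*% beta) + noiseSd * dat$eps
  gp <- GenoPheno(dat$x, phenotype = y)
  S4Vectors::metadata(gp) <- list(design = "example1", influential = 1:4,
                                  coefficients = beta, rho = rho, seed = seed)
  gp
}

#' Generate the second validation design: equicorrelated SNPs with additive
#' and dominant effects
#'
#' Latent equicorrelated standard normals (pairwise correlation 0.1, realised
#' through one shared factor) are cut at plus/minus the standard-normal third
#' quartile into genotype codes 2/1/0 with frequencies (1/4, 1/2, 1/4). Five
#' influential SNPs at positions 100, 200, ..., 500 act through additive
#' (`AA -> 1, Aa -> 0, aa -> -1`) and dominant (`Aa -> 1, else 0`) recodings
#' with effect pairs (1.2, 0.8), (1.2, 0.4), (1.2, 0.8), (0.8, 1.2),
#' (1.0, 1.2); the returned matrix holds the genotype codes that screening
#' operates on, not the recodings.
#'
#' @param n,p dimensions (p >= 500).
#' @param seed generator seed.
#' @param noiseSd noise standard deviation.
#' @return A [GenoPheno-class] with design metadata.
#' @export
genExample2 <- function(n = 200L, p = 5000L, seed = 1L, noiseSd = 1) {
  if (p < 500) stop("example2 needs p >= 500 (influential indices reach 500)")
  rho <- 0.1
  dat <- withSeed(seed, {
    g <- rnorm(n)
    u <- sqrt(rho) * g + sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    eps <- rnorm(n)
    list(u = u, eps = eps)
  })
  x <- cutGenotypes(dat$u)
  inf <- c(100L, 200L, 300L, 400L, 500L)
  bAdd <- c(1.2, 1.2, 1.2, 0.8, 1.0)
  bDom <- c(0.8, 0.4, 0.8, 1.2, 1.2)
  xa <- x[, inf, drop = FALSE] - 1            # additive recode: (2,1,0) -> (1,0,-1)
  xd <- 1 * (x[, inf, drop = FALSE] == 1)     # dominant recode: Aa -> 1
  y <- drop(xa %*% bAdd) + drop(xd %*% bDom) + noiseSd * dat$eps
  gp <- GenoPheno(x, phenotype = y)
  S4Vectors::metadata(gp) <- list(design = "example2", influential = inf,
                                  additive = bAdd, dominant = bDom, seed = seed)
  gp
}

#' Generate the third validation design: AR(1)-linked SNPs, weak indicator
#' effects
#'
#' Latent standard normals follow an AR(1) dependence with parameter 0.2
#' (sampled by the exact recursion `u_j = 0.2 u_{j-1} + sqrt(1 - 0.04) z_j`)
#' and are cut into genotypes as in the second design. Ten influential SNPs at
#' positions 100, 200, ..., 1000 act through
#' \deqn{y = \sum_j \beta_j I(X_j = 1) + 2\beta_j I(X_j = 2) + \epsilon,}
#' with `beta_j` drawn once per dataset from Uniform(2, 3) — much weaker
#' signals than the first design.
#'
#' @param n,p dimensions (p >= 1000).
#' @param seed generator seed.
#' @param noiseSd noise standard deviation.
#' @return A [GenoPheno-class] with design metadata (including the drawn
#'   `beta`).
#' @export
genExample3 <- function(n = 200L, p = 2000L, seed = 1L, noiseSd = 1) {
  if (p < 1000) stop("example3 needs p >= 1000 (influential indices reach 1000)")
  phi <- 0.2
  dat <- withSeed(seed, {
    z <- matrix(rnorm(n * p), n, p)
    beta <- runif(10, 2, 3)
    eps <- rnorm(n)
    list(z = z, beta = beta, eps = eps)
  })
  u <- dat$z
  s <- sqrt(1 - phi^2)
  for (j in 2:p) u[, j] <- phi * u[, j - 1] + s * dat$z[, j]
  x <- cutGenotypes(u)
  inf <- seq(100L, 1000L, by = 100L)
  xi <- x[, inf, drop = FALSE]
  y <- drop((1 * (xi == 1)) %*% dat$beta) + drop((1 * (xi == 2)) %*% (2 * dat$beta)) +
    noiseSd * dat$eps
  gp <- GenoPheno(x, phenotype = y)
  S4Vectors::metadata(gp) <- list(design = "example3", influential = inf,
                                  beta = dat$beta, seed = seed)
  gp
}

#' Materialise a SimulationDesign into a dataset
#'
#' @param design a [SimulationDesign-class].
#' @param seed optional override of the design's seed.
#' @return A [GenoPheno-class].
#' @export
generateDesign <- function(design, seed = NULL) {
  if (is.null(seed)) seed <- design@seed
  switch(design@name,
    example1 = genExample1(design@n, design@p, rho = design@correlation,
                           seed = seed, noiseSd = design@noiseSd),
    example2 = genExample2(design@n, design@p, seed = seed,
                           noiseSd = design@noiseSd),
    example3 = genExample3(design@n, design@p, seed = seed,
                           noiseSd = design@noiseSd))
}

# 5-fold CV MSPE of a SCAD model on the given feature subset: outer folds are
# held out, the lambda is chosen by inner CV on each outer training part.
cvMspeScad <- function(x, y, config = scadConfig(), nFolds = 5L) {
  n <- nrow(x)
  foldid <- sample(rep_len(seq_len(nFolds), n))
  sse <- 0
  for (f in seq_len(nFolds)) {
    train <- which(foldid != f)
    test <- which(foldid == f)
    inner <- sample(rep_len(seq_len(config@cvFolds), length(train)))
    sse <- sse + scadCvPredictMspe(x, y, train, inner, test, config) * length(test)
  }
  sse / n
}

#' Replicate evaluation of a screening method on a validation design
#'
#' Runs the chosen method on independently generated replicates of a design
#' and summarises performance by the criteria used throughout the feature
#' screening literature: the average estimated threshold, the strict power
#' (fraction of replicates in which every influential feature is selected),
#' per-feature individual powers, and the mean 5-fold cross-validated MSPE of
#' a SCAD model refitted on each replicate's selected features.
#'
#' @param method `"dcsis"` or `"idcsis"` (fixed threshold `fixedD` required)
#'   or `"beidc"` (adaptive threshold; `fixedD` ignored).
#' @param design a [SimulationDesign-class].
#' @param nReplicates number of replicates (>= 1).
#' @param fixedD fixed model size for the screening-only methods, e.g.
#'   `fixedThreshold(n, 2)`.
#' @param config a [BeConfig-class] (used by `"beidc"`, and its `scad` slot by
#'   the CV-MSPE summary).
#' @param schedule iteration schedule for the iterative methods; the default
#'   is the three-step prescription (3, 3, rest).
#' @param computeMspe set FALSE to skip the CV-MSPE summary (screening-only
#'   studies).
#' @param verbose log per-replicate progress.
#' @return An [EvaluationReport-class].
#' @export
evaluateMethod <- function(method = c("dcsis", "idcsis", "beidc"), design,
                           nReplicates = 100L, fixedD = NULL,
                           config = beConfig(),
                           schedule = iterationSchedule(c(3L, 3L), 6L),
                           computeMspe = TRUE, verbose = FALSE) {
  method <- match.arg(method)
  if (nReplicates < 1) stop("nReplicates must be at least 1")
  if (method %in% c("dcsis", "idcsis") && is.null(fixedD))
    stop("fixedD is required for the fixed-threshold methods")
  inf <- design@influentialIndices
  hits <- matrix(FALSE, nReplicates, length(inf))
  dHats <- numeric(nReplicates)
  mspes <- rep(NA_real_, nReplicates)
  for (r in seq_len(nReplicates)) {
    dataSeed <- childSeed(design@seed, r)
    gp <- generateDesign(design, seed = dataSeed)
    x <- featureMatrix(gp)
    y <- phenotype(gp)
    if (method == "beidc") {
      cfg <- config
      cfg@seed <- childSeed(dataSeed, 104729L)
      res <- beidcCore(x, y, cfg, schedule, featureIds = colnames(x))
      selIdx <- match(res@threshold@selected, colnames(x))
      dHats[r] <- res@threshold@dHat
    } else {
      rk <- if (method == "dcsis") dcsisRank(x, y)
            else idcsisRank(x, y, schedule = schedule)
      selIdx <- rk@order[seq_len(min(fixedD, ncol(x)))]
      dHats[r] <- fixedD
    }
    hits[r, ] <- inf %in% selIdx
    if (computeMspe) {
      mspes[r] <- withSeed(childSeed(dataSeed, 9973L),
                           cvMspeScad(x[, selIdx, drop = FALSE], y,
                                      config = config@scad))
    }
    if (verbose)
      message(sprintf("replicate %d/%d: d = %d, all influential = %s",
                      r, nReplicates, dHats[r], all(hits[r, ])))
  }
  methods::new("EvaluationReport",
               averageThreshold = mean(dHats),
               strictPower = mean(apply(hits, 1, all)),
               individualPower = setNames(colMeans(hits), paste0("P_", inf)),
               cvMspe = if (computeMspe) mean(mspes) else NA_real_,
               nReplicates = as.integer(nReplicates))
}
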