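#' Squared distance covariance (pairwise-distance V-statistic)
#'
#' Plug-in estimator of the squared distance covariance between two
#' univariate samples, computed from the pairwise absolute differences as
#' \deqn{\widehat{dcov}^2 = \hat S_1 + \hat S_2 - 2\hat S_3,} where
#' \eqn{\hat S_1} is the mean of the products of the two distance matrices,
#' \eqn{\hat S_2} the product of their means, and \eqn{\hat S_3} the mean of
#' the products of their row means. The statistic is non-negative up to
#' rounding; negative floating-point residue is clamped to 0.
#'
#' @param x,y numeric vectors of equal length (at least 2), finite entries.
#' @return Non-negative scalar.
#' @examples
#' dcov2Hat(c(0, 1, 2, 3), c(0, 1, 2, 3))
#' @export
dcov2Hat <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("entries must be finite")
  cpp_dcov2(x, y)
}

#' Distance correlation between two univariate samples
#'
#' \deqn{\widehat{Dcorr}(x, y) = \sqrt{\frac{\widehat{dcov}^2(x,y)}
#'   {\sqrt{\widehat{dcov}^2(x,x)\,\widehat{dcov}^2(y,y)}}},}
#' in \eqn{[0, 1]}; defined as 0 when either marginal squared distance
#' covariance vanishes (constant input).
#'
#' @inheritParams dcov2Hat
#' @return Scalar in `[0, 1]`.
#' @examples
#' y <- rnorm(20)
#' dcorrHat(y, y)  # 1 for any non-constant sample
#' @export
dcorrHat <- function(x, y) {
  vxy <- dcov2Hat(x, y)
  vxx <- dcov2Hat(x, x)
  vyy <- dcov2Hat(y, y)
  if (vxx <= 0 || vyy <= 0) return(0)
  r2 <- vxy / sqrt(vxx * vyy)
  sqrt(min(max(r2, 0), 1))
}

# Squared distance correlations of all columns of x against y (C++ kernel);
# ranking uses the squared scale (monotone-equivalent), reported scores are
# square-rooted back to the Dcorr scale.
dcorScoreVector <- function(x, y) {
  storage.mode(x) <- "double"
  cpp_dcor2_scores(x, as.numeric(y))
}

# Shared assembly: order by descending score with ties broken by ascending
# original index (order() is stable for the secondary key).
makeRanking <- function(scores2, stage, featureIds) {
  ord <- order(-scores2, seq_along(scores2))
  methods::new("ScreenRanking", order = as.integer(ord),
               scores = sqrt(pmin(pmax(scores2, 0), 1)),
               stage = as.integer(stage),
               featureIds = as.character(featureIds))
}

checkScreenInput <- function(x, y) {
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 2) stop("need at least 2 samples")
  if (length(y) != nrow(x)) stop("phenotype length must equal the sample count")
  if (anyNA(x) || any(!is.finite(x))) stop("features must be finite")
  if (any(!is.finite(y))) stop("phenotype must be finite")
  x
}

#' @describeIn dcsisRank single-pass DC-SIS on a samples-by-features matrix.
#' @aliases dcsisRank,matrix-method
#' @param featureIds optional feature labels (default: column names).
#' @export
setMethod("dcsisRank", signature(x = "matrix", y = "numeric"),
  function(x, y, featureIds = NULL, ...) {
    x <- checkScreenInput(x, y)
    if (is.null(featureIds)) {
      featureIds <- colnames(x)
      if (is.null(featureIds)) featureIds <- paste0("snp", seq_len(ncol(x)))
    }
    s2 <- dcorScoreVector(x, y)
    makeRanking(s2, rep(0L, ncol(x)), featureIds)
  })

#' Marginal DC-SIS ranking
#'
#' Ranks every feature by its estimated distance correlation with the
#' phenotype, from the most to the least influential. Ties are broken by the
#' original feature index; zero-variance (monomorphic) features score 0 and
#' sink to the bottom.
#'
#' @name dcsisRank
#' @param x samples-by-features matrix or [GenoPheno-class].
#' @param y numeric phenotype (taken from the container for `GenoPheno`).
#' @param ... passed on.
#' @return A [ScreenRanking-class] with `stage = 0` throughout.
#' @examples
#' x <- matrix(rnorm(200), 20, 10)
#' y <- 2 * x[, 1] + rnorm(20, sd = 0.1)
#' rankedFeatures(dcsisRank(x, y))[1]
NULL

#' @describeIn dcsisRank container method; phenotype is read from `colData`.
#' @export
setMethod("dcsisRank", signature(x = "GenoPheno", y = "missing"),
  function(x, y, ...) {
    ph <- phenotype(x)
    if (is.null(ph)) stop("GenoPheno carries no phenotype")
    dcsisRank(featureMatrix(x), ph, featureIds = featureIds(x), ...)
  })
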