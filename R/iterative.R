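#' Residualise features on a selected block
#'
#' Returns the component of each remaining column orthogonal to the column
#' space of the selected block, i.e. applies the annihilator
#' \eqn{I_n - X_p (X_p^T X_p)^{-} X_p^T} to the complement set. The projector
#' is built from a singular value decomposition, so rank-deficient selected
#' blocks (perfectly linked SNPs) behave as the pseudo-inverse projection.
#' With `center = TRUE` (default) an implicit intercept column joins the
#' projection basis, removing mean effects.
#'
#' @param selected n-by-k matrix of already-selected features (k >= 1).
#' @param remaining n-by-m matrix of features to be residualised.
#' @param center include an intercept column in the projection basis.
#' @return n-by-m matrix of residuals; idempotent (residualising twice equals
#'   once, up to rounding).
#' @examples
#' residualize(matrix(1, 3, 1), matrix(1:3, 3, 1))  # (-1, 0, 1)
#' @export
residualize <- function(selected, remaining, center = TRUE) {
  selected <- as.matrix(selected)
  remaining <- as.matrix(remaining)
  if (ncol(selected) < 1)
    stop("selected must contain at least one column; skip residualisation instead")
  if (nrow(selected) != nrow(remaining))
    stop("selected and remaining must have the same number of rows")
  basis <- if (center) cbind(1, selected) else selected
  sv <- svd(basis, nv = 0)
  keep <- sv$d > max(dim(basis)) * .Machine$double.eps * sv$d[1]
  U <- sv$u[, keep, drop = FALSE]
  out <- remaining - U %*% crossprod(U, remaining)
  dimnames(out) <- dimnames(remaining)
  out
}

# Expand a schedule into explicit iterative block sizes for p features:
# the declared blocks first, then the last declared size repeated until
# min(iterativeCap, p) features are covered (the final partial block is
# trimmed).  Features beyond the cap are ranked in one closing single-pass
# sweep on their residuals.
expandBlocks <- function(schedule, p) {
  target <- min(schedule@iterativeCap, p)
  sizes <- integer(0)
  declared <- schedule@blockSizes
  last <- declared[length(declared)]
  i <- 1L
  covered <- 0L
  while (covered < target) {
    b <- if (i <= length(declared)) declared[i] else last
    b <- min(b, target - covered)
    sizes <- c(sizes, b)
    covered <- covered + b
    i <- i + 1L
  }
  sizes
}

#' @describeIn idcsisRank matrix method.
#' @aliases idcsisRank,matrix-method
#' @param featureIds optional feature labels (default: column names).
#' @param center include an implicit intercept in the projection basis
#'   (disable to apply the raw annihilator).
#' @export
setMethod("idcsisRank", signature(x = "matrix", y = "numeric"),
  function(x, y, schedule = iterationSchedule(), featureIds = NULL,
           center = TRUE, ...) {
    x <- checkScreenInput(x, y)
    p <- ncol(x)
    if (is.null(featureIds)) {
      featureIds <- colnames(x)
      if (is.null(featureIds)) featureIds <- paste0("snp", seq_len(p))
    }
    blocks <- expandBlocks(schedule, p)
    if (p <= blocks[1]) return(dcsisRank(x, y, featureIds = featureIds))

    ordOut <- integer(0)
    scores <- numeric(p)
    stage <- integer(p)
    remaining <- seq_len(p)
    for (s in seq_along(blocks)) {
      if (s == 1L) {
        s2 <- dcorScoreVector(x, y)
      } else {
        res <- residualize(x[, ordOut, drop = FALSE],
                           x[, remaining, drop = FALSE], center = center)
        s2 <- numeric(p)
        s2[remaining] <- dcorScoreVector(res, y)
      }
      cand <- remaining[order(-s2[remaining], remaining)]
      take <- cand[seq_len(min(blocks[s], length(cand)))]
      scores[take] <- sqrt(pmin(pmax(s2[take], 0), 1))
      stage[take] <- s
      ordOut <- c(ordOut, take)
      remaining <- setdiff(remaining, take)
      if (!length(remaining)) break
    }
    if (length(remaining)) {
      res <- residualize(x[, ordOut, drop = FALSE],
                         x[, remaining, drop = FALSE], center = center)
      s2 <- dcorScoreVector(res, y)
      fin <- remaining[order(-s2, remaining)]
      scores[remaining] <- sqrt(pmin(pmax(s2, 0), 1))
      stage[remaining] <- length(blocks) + 1L
      ordOut <- c(ordOut, fin)
    }
    methods::new("ScreenRanking", order = as.integer(ordOut), scores = scores,
                 stage = stage, featureIds = as.character(featureIds))
  })

#' Iterative DC-SIS ranking (IDC-SIS)
#'
#' Stage 1 ranks all features by marginal distance correlation and retains the
#' first block. Every later stage residualises the not-yet-selected features
#' on the cumulative selected set, re-ranks the residuals by distance
#' correlation with the phenotype, and retains the next block — recovering
#' jointly-important but marginally-silent features and breaking rankings
#' inflated by linkage disequilibrium. Once `iterativeCap` features have been
#' ranked iteratively, all remaining features are ordered in one final
#' single-pass sweep on their residuals. Fully deterministic.
#'
#' @name idcsisRank
#' @param x samples-by-features matrix or [GenoPheno-class].
#' @param y numeric phenotype (taken from the container for `GenoPheno`).
#' @param schedule an [IterationSchedule-class]; the default ranks blocks of
#'   3 iteratively up to 100 features. `iterationSchedule(c(3, 3), 6)` gives
#'   the three-step schedule (3, 3, p - 6).
#' @param ... passed on.
#' @return A [ScreenRanking-class]; `screenStage()` records the stage that
#'   ranked each feature.
NULL

#' @describeIn idcsisRank container method.
#' @export
setMethod("idcsisRank", signature(x = "GenoPheno", y = "missing"),
  function(x, y, schedule = iterationSchedule(), ...) {
    ph <- phenotype(x)
    if (is.null(ph)) stop("GenoPheno carries no phenotype")
    idcsisRank(featureMatrix(x), ph, schedule = schedule,
               featureIds = featureIds(x), ...)
  })
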