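#' One backward-elimination step
#'
#' Next pool size after discarding `dropRate` of the current pool (the
#' lowest-ranked features): `poolSize - ceiling(dropRate * poolSize)`, floored
#' at `minPool`, and forced to decrease by at least one. From any start the
#' sequence reaches `minPool` in finitely many steps.
#'
#' @param poolSize current pool size (positive integer).
#' @param dropRate fraction in (0, 1).
#' @param minPool smallest admissible pool size.
#' @return The next pool size.
#' @examples
#' eliminateStep(5000, 0.5)  # 2500
#' eliminateStep(3, 0.5)     # 1
#' @export
eliminateStep <- function(poolSize, dropRate, minPool = 1L) {
  if (poolSize < 1) stop("poolSize must be positive")
  nxt <- poolSize - as.integer(ceiling(dropRate * poolSize))
  if (nxt >= poolSize) nxt <- poolSize - 1L
  max(as.integer(minPool), as.integer(nxt))
}

#' Bootstrap out-of-bag MSPE of a SCAD model on a feature pool
#'
#' For each bootstrap resample (drawn with replacement), the SCAD regression
#' is fitted by cross-validated lambda selection on the in-bag training data —
#' the drawn multiset itself, so a row drawn twice carries double weight in
#' the fit and in the inner CV — and evaluated on the out-of-bag rows; the
#' mean squared prediction errors are averaged over resamples. Resamples with
#' an empty out-of-bag set are redrawn. When called standalone the indices are
#' drawn from a substream of the seeded generator keyed by `streamKey`, so
#' results are fully deterministic given `config@seed` and enlarging
#' `nBootstrap` only appends replicates; [runBeIdc()] instead supplies one
#' shared `resamples` set so that all pools are scored on the same draws.
#'
#' @param x n-by-k numeric matrix, the candidate pool (k >= 1, n >= 10).
#' @param y numeric phenotype.
#' @param config a [BeConfig-class].
#' @param streamKey integer labelling the substream (defaults to the pool
#'   size) when `resamples` are not supplied.
#' @param resamples optional pre-drawn resamples from [drawBootstrap()]; the
#'   backward-elimination driver draws one set and scores every pool on it
#'   (common random numbers), so pool comparisons are paired.
#' @return List with `mean`, `se` (standard deviation across resamples divided
#'   by `sqrt(nBootstrap)`) and the per-resample `mspe` vector.
#' @export
bootstrapMspe <- function(x, y, config = beConfig(), streamKey = ncol(x),
                          resamples = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (ncol(x) < 1) stop("the pool must contain at least one feature")
  if (n < 10) stop("need at least 10 observations for the OOB bootstrap")
  if (length(y) != n) stop("phenotype length must equal nrow(x)")
  y <- as.numeric(y)
  nLambdaCap <- if (ncol(x) > 20 * n) 25L else NULL
  if (is.null(resamples))
    resamples <- withSeed(childSeed(config@seed, 7919 * streamKey),
                          drawBootstrap(n, config@nBootstrap,
                                        config@scad@cvFolds))
  B <- length(resamples)
  mspe <- numeric(B)
  for (b in seq_len(B)) {
    rs <- resamples[[b]]
    mspe[b] <- scadCvPredictMspe(x, y, rs$idx, rs$foldid, rs$oob, config@scad,
                                 nLambdaCap)
  }
  se <- if (B > 1) stats::sd(mspe) / sqrt(B) else 0
  list(mean = mean(mspe), se = se, mspe = mspe)
}

#' Draw bootstrap resamples with their inner CV fold assignments
#'
#' Each resample is a with-replacement draw of all n rows (redrawn if no row
#' is left out of bag), an out-of-bag complement, and a fold assignment for
#' the inner cross-validation. Drawn from the current RNG stream.
#'
#' @param n sample count.
#' @param B number of resamples.
#' @param nfolds inner CV folds.
#' @return List of `B` lists with elements `idx`, `oob`, `foldid`.
#' @export
drawBootstrap <- function(n, B, nfolds = 5L) {
  lapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) < n) break
    }
    list(idx = idx, oob = setdiff(seq_len(n), idx),
         foldid = sample(rep_len(seq_len(nfolds), n)))
  })
}

#' Adaptive threshold from an elimination trace
#'
#' Pure function of the trace: the threshold is the visited pool size with the
#' smallest mean MSPE (exact ties resolved towards the smaller size), and the
#' 1-s.e. alternative is the smallest visited size whose mean MSPE lies within
#' one standard error (taken at the minimising size) of the minimum.
#'
#' @param trace an [EliminationTrace-class].
#' @return A [ThresholdResult-class].
#' @export
selectThreshold <- function(trace) {
  if (!methods::is(trace, "EliminationTrace")) stop("trace must be an EliminationTrace")
  m <- trace@mspeMean
  if (!length(m)) stop("trace must be non-empty")
  best <- max(which(m == min(m)))  # poolSizes decrease, so max index = smallest size
  thr <- m[best] + trace@mspeSe[best]
  eligible <- which(m <= thr)
  oneSe <- which(trace@poolSizes == min(trace@poolSizes[eligible]))
  selected <- trace@pools[[best]]
  allIds <- trace@pools[[1]]
  methods::new("ThresholdResult",
               dHat = trace@poolSizes[best],
               selected = as.character(selected),
               discarded = as.character(setdiff(allIds, selected)),
               dOneSe = trace@poolSizes[oneSe],
               mspeAtDHat = m[best])
}

beidcCore <- function(x, y, config, schedule, featureIds, center = TRUE,
                      verbose = FALSE) {
  ranking <- idcsisRank(x, y, schedule = schedule, featureIds = featureIds,
                        center = center)
  rankedIdx <- ranking@order
  rankedIds <- ranking@featureIds[rankedIdx]
  p <- ncol(x)
  sizes <- p
  while (sizes[length(sizes)] > config@minPool)
    sizes <- c(sizes, eliminateStep(sizes[length(sizes)], config@dropRate,
                                    config@minPool))
  # one set of resamples, shared by every pool: pool-to-pool MSPE
  # comparisons are paired, so resampling noise largely cancels in the argmin
  resamples <- withSeed(childSeed(config@seed, 1L),
                        drawBootstrap(nrow(x), config@nBootstrap,
                                      config@scad@cvFolds))
  mMean <- mSe <- numeric(length(sizes))
  for (i in seq_along(sizes)) {
    k <- sizes[i]
    if (verbose)
      message(sprintf("pool size %d (%d/%d)", k, i, length(sizes)))
    bm <- bootstrapMspe(x[, rankedIdx[seq_len(k)], drop = FALSE], y,
                        config = config, resamples = resamples)
    mMean[i] <- bm$mean
    mSe[i] <- bm$se
  }
  trace <- methods::new("EliminationTrace", poolSizes = as.integer(sizes),
                        mspeMean = mMean, mspeSe = mSe,
                        pools = lapply(sizes, function(k) rankedIds[seq_len(k)]))
  methods::new("BeIdcResult", ranking = ranking, trace = trace,
               threshold = selectThreshold(trace))
}

#' @describeIn runBeIdc matrix method.
#' @aliases runBeIdc,matrix-method
#' @param featureIds optional feature labels (default: column names).
#' @param center include an implicit intercept in the residualisation basis.
#' @param verbose log each visited pool size.
#' @export
setMethod("runBeIdc", signature(x = "matrix", y = "numeric"),
  function(x, y, config = beConfig(), schedule = iterationSchedule(),
           featureIds = NULL, center = TRUE, verbose = FALSE, ...) {
    x <- checkScreenInput(x, y)
    if (is.null(featureIds)) {
      featureIds <- colnames(x)
      if (is.null(featureIds)) featureIds <- paste0("snp", seq_len(ncol(x)))
    }
    beidcCore(x, as.numeric(y), config, schedule, featureIds, center, verbose)
  })

#' Backward-elimination iterative distance-correlation selection (BE-IDC)
#'
#' The full adaptive-threshold procedure: (1) rank all features once by
#' [idcsisRank()]; (2) starting from the full pool, repeatedly score the
#' current top-ranked pool by [bootstrapMspe()] and discard `dropRate` of its
#' lowest-ranked members ([eliminateStep()]) until the pool cannot shrink;
#' (3) take the visited pool size minimising the mean out-of-bag MSPE as the
#' adaptive threshold ([selectThreshold()]). The ranking is frozen after step
#' 1; elimination never re-ranks, and every pool is refitted from scratch.
#'
#' @name runBeIdc
#' @param x samples-by-features matrix or [GenoPheno-class].
#' @param y numeric phenotype (taken from the container for `GenoPheno`).
#' @param config a [BeConfig-class].
#' @param schedule an [IterationSchedule-class] for the ranking step.
#' @param ... passed to methods.
#' @return A [BeIdcResult-class] bundling the ranking, the elimination trace
#'   and the threshold result.
NULL

#' @describeIn runBeIdc container method.
#' @export
setMethod("runBeIdc", signature(x = "GenoPheno", y = "missing"),
  function(x, y, config = beConfig(), schedule = iterationSchedule(), ...) {
    ph <- phenotype(x)
    if (is.null(ph)) stop("GenoPheno carries no phenotype")
    runBeIdc(featureMatrix(x), ph, config = config, schedule = schedule,
             featureIds = featureIds(x), ...)
  })
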