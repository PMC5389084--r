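#' GenoPheno: genotype dosage matrix plus a continuous phenotype
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `"dosage"` assay (features in rows, samples in columns; SNP codes 0/1/2 or
#' continuous covariates) and, optionally, a numeric `phenotype` column in
#' `colData`. Optional genomic coordinates (chromosome, 1-based bp position)
#' live in `rowData`.
#'
#' @slot .. see `SummarizedExperiment`; no additional slots.
#' @aliases GenoPheno-class
#' @exportClass GenoPheno
setClass("GenoPheno", contains = "SummarizedExperiment")

setValidity("GenoPheno", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    m <- SummarizedExperiment::assay(object, "dosage")
    if (ncol(m) < 2) msg <- c(msg, "need at least 2 samples")
    if (nrow(m) < 1) msg <- c(msg, "need at least 1 feature")
    if (anyNA(m) || any(!is.finite(m)))
      msg <- c(msg, "dosage values must be finite and non-missing (impute at I/O)")
    if (anyDuplicated(rownames(m))) msg <- c(msg, "feature ids must be unique")
  }
  ph <- object$phenotype
  if (!is.null(ph)) {
    if (length(ph) != ncol(object))
      msg <- c(msg, "phenotype length must equal the sample count")
    if (any(!is.finite(ph))) msg <- c(msg, "phenotype must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenoPheno object
#'
#' @param genotypes numeric matrix, samples in rows and features in columns
#'   (the orientation screening operates on); coerced to the internal
#'   features-by-samples assay.
#' @param phenotype optional numeric vector, one value per sample.
#' @param featureIds,sampleIds identifiers; default to dimnames or generated.
#' @param coords optional `data.frame` with columns `chrom` and `pos`
#'   (1-based bp), one row per feature.
#' @return A [GenoPheno-class] object.
#' @examples
#' gp <- GenoPheno(matrix(rbinom(40, 2, 0.5), nrow = 10), phenotype = rnorm(10))
#' nFeatures(gp)
#' @export
GenoPheno <- function(genotypes, phenotype = NULL, featureIds = NULL,
                      sampleIds = NULL, coords = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (!is.null(phenotype) && length(phenotype) != nrow(genotypes))
    stop("phenotype length must equal the sample count")
  if (is.null(featureIds)) {
    featureIds <- colnames(genotypes)
    if (is.null(featureIds)) featureIds <- paste0("snp", seq_len(ncol(genotypes)))
  }
  if (is.null(sampleIds)) {
    sampleIds <- rownames(genotypes)
    if (is.null(sampleIds)) sampleIds <- paste0("sample", seq_len(nrow(genotypes)))
  }
  mat <- t(genotypes)
  dimnames(mat) <- list(featureIds, sampleIds)
  rd <- if (is.null(coords)) S4Vectors::DataFrame(row.names = featureIds)
        else S4Vectors::DataFrame(chrom = coords$chrom, pos = as.integer(coords$pos),
                                  row.names = featureIds)
  cd <- if (is.null(phenotype)) S4Vectors::DataFrame(row.names = sampleIds)
        else S4Vectors::DataFrame(phenotype = as.numeric(phenotype),
                                  row.names = sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(dosage = mat), rowData = rd, colData = cd)
  methods::new("GenoPheno", se)
}

#' ScreenRanking: output of a (possibly iterative) DC-SIS ranking
#'
#' @slot order integer permutation of `1:p`, most to least important.
#' @slot scores numeric, estimated distance correlations on the Dcorr scale,
#'   aligned with the original feature index.
#' @slot stage integer per feature: which screening stage ranked it
#'   (0 throughout for a single-pass DC-SIS ranking).
#' @slot featureIds character feature labels, original order.
#' @exportClass ScreenRanking
setClass("ScreenRanking",
         representation(order = "integer", scores = "numeric",
                        stage = "integer", featureIds = "character"))

setValidity("ScreenRanking", function(object) {
  p <- length(object@scores)
  msg <- character()
  if (!identical(sort(object@order), seq_len(p)))
    msg <- c(msg, "order must be a permutation of 1..p")
  if (length(object@stage) != p) msg <- c(msg, "stage must align with scores")
  if (any(object@scores < 0 | object@scores > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  so <- object@scores[object@order]
  st <- object@stage[object@order]
  for (s in unique(st)) {
    v <- so[st == s]
    if (any(diff(v) > 1e-12))
      msg <- c(msg, "scores must be non-increasing along the order within a stage")
  }
  if (length(object@featureIds) && length(object@featureIds) != p)
    msg <- c(msg, "featureIds must align with scores")
  if (length(msg)) msg else TRUE
})

#' IterationSchedule: block structure of the iterative screen
#'
#' `blockSizes` gives the explicit sizes of the first iterative blocks; after
#' they are exhausted the last size is repeated until `iterativeCap` features
#' have been ranked iteratively, and the remaining features are then ranked in
#' one final single-pass sweep on their residuals.
#'
#' @slot blockSizes integer vector of positive block sizes.
#' @slot iterativeCap integer, number of features ranked iteratively.
#' @exportClass IterationSchedule
setClass("IterationSchedule",
         representation(blockSizes = "integer", iterativeCap = "integer"))

setValidity("IterationSchedule", function(object) {
  msg <- character()
  if (length(object@blockSizes) < 1 || any(object@blockSizes < 1))
    msg <- c(msg, "blockSizes must be positive integers")
  need <- sum(object@blockSizes[seq_len(min(2L, length(object@blockSizes)))])
  if (object@iterativeCap < need)
    msg <- c(msg, "iterativeCap must cover at least the first two blocks")
  if (length(msg)) msg else TRUE
})

#' @rdname IterationSchedule-class
#' @param blockSizes,iterativeCap see slots.
#' @return An `IterationSchedule`.
#' @export
iterationSchedule <- function(blockSizes = c(3L, 3L), iterativeCap = 100L) {
  methods::new("IterationSchedule", blockSizes = as.integer(blockSizes),
               iterativeCap = as.integer(iterativeCap))
}

#' ScadConfig: tuning of the SCAD coordinate-descent solver
#'
#' @slot alpha SCAD shape parameter (> 2; 3.7 by convention).
#' @slot nLambda number of grid points when the lambda path is auto-generated.
#' @slot lambdaMinRatio smallest grid lambda as a fraction of lambda_max.
#' @slot lambdaGrid optional explicit decreasing grid (length 0 = auto).
#' @slot cvFolds folds for cross-validated lambda selection.
#' @slot maxIter coordinate-descent sweep budget per lambda.
#' @slot tol convergence tolerance on the standardised coefficients.
#' @slot dfMax saturation guard: the lambda path stops once a solution carries
#'   more than this many nonzero coefficients (`NA` = the number of training
#'   observations, i.e. stop at saturation; relevant only when k >> n).
#' @exportClass ScadConfig
setClass("ScadConfig",
         representation(alpha = "numeric", nLambda = "integer",
                        lambdaMinRatio = "numeric", lambdaGrid = "numeric",
                        cvFolds = "integer", maxIter = "integer", tol = "numeric",
                        dfMax = "numeric"))

setValidity("ScadConfig", function(object) {
  msg <- character()
  if (object@alpha <= 2) msg <- c(msg, "alpha must exceed 2")
  if (object@cvFolds < 2) msg <- c(msg, "cvFolds must be at least 2")
  if (length(object@lambdaGrid) && any(object@lambdaGrid <= 0))
    msg <- c(msg, "lambdaGrid must be strictly positive")
  if (length(msg)) msg else TRUE
})

#' @rdname ScadConfig-class
#' @param alpha,nLambda,lambdaMinRatio,lambdaGrid,cvFolds,maxIter,tol,dfMax see
#'   slots.
#' @return A `ScadConfig`.
#' @export
scadConfig <- function(alpha = 3.7, nLambda = 50L, lambdaMinRatio = 0.01,
                       lambdaGrid = numeric(), cvFolds = 5L,
                       maxIter = 1000L, tol = 1e-5, dfMax = NA_real_) {
  methods::new("ScadConfig", alpha = alpha, nLambda = as.integer(nLambda),
               lambdaMinRatio = lambdaMinRatio, lambdaGrid = as.numeric(lambdaGrid),
               cvFolds = as.integer(cvFolds), maxIter = as.integer(maxIter),
               tol = tol, dfMax = as.numeric(dfMax))
}

#' ScadFit: a fitted SCAD-penalised regression
#'
#' @slot intercept,beta coefficients on the original feature scale.
#' @slot lambdaSelected penalty level of this fit.
#' @slot nonzeroIndexSet indices with nonzero coefficients.
#' @slot converged logical; FALSE when the sweep budget was exhausted.
#' @slot objective per-sweep objective trace (single-lambda fits only).
#' @exportClass ScadFit
setClass("ScadFit",
         representation(intercept = "numeric", beta = "numeric",
                        lambdaSelected = "numeric", nonzeroIndexSet = "integer",
                        converged = "logical", objective = "numeric"))

#' BeConfig: backward-elimination configuration
#'
#' @slot dropRate fraction of the current pool discarded per step, in (0,1).
#' @slot nBootstrap bootstrap resamples per pool size.
#' @slot minPool smallest pool size visited.
#' @slot seed base seed; every source of randomness derives from it.
#' @slot scad a [ScadConfig-class].
#' @exportClass BeConfig
setClass("BeConfig",
         representation(dropRate = "numeric", nBootstrap = "integer",
                        minPool = "integer", seed = "integer", scad = "ScadConfig"))

setValidity("BeConfig", function(object) {
  msg <- character()
  if (object@dropRate <= 0 || object@dropRate >= 1)
    msg <- c(msg, "dropRate must lie strictly between 0 and 1")
  if (object@nBootstrap < 1) msg <- c(msg, "nBootstrap must be positive")
  if (object@minPool < 1) msg <- c(msg, "minPool must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname BeConfig-class
#' @param dropRate,nBootstrap,minPool,seed,scad see slots.
#' @return A `BeConfig`.
#' @export
beConfig <- function(dropRate = 0.5, nBootstrap = 1000L, minPool = 1L,
                     seed = 1L, scad = scadConfig()) {
  methods::new("BeConfig", dropRate = dropRate, nBootstrap = as.integer(nBootstrap),
               minPool = as.integer(minPool), seed = as.integer(seed), scad = scad)
}

#' EliminationTrace: the MSPE-versus-pool-size curve
#'
#' @slot poolSizes strictly decreasing pool sizes, from p down to minPool.
#' @slot mspeMean,mspeSe bootstrap mean MSPE and its standard error per pool.
#' @slot pools list of character vectors: the ranked feature-id prefix
#'   constituting each pool.
#' @exportClass EliminationTrace
setClass("EliminationTrace",
         representation(poolSizes = "integer", mspeMean = "numeric",
                        mspeSe = "numeric", pools = "list"))

setValidity("EliminationTrace", function(object) {
  msg <- character()
  k <- length(object@poolSizes)
  if (k < 1) msg <- c(msg, "trace must be non-empty")
  if (k > 1 && any(diff(object@poolSizes) >= 0))
    msg <- c(msg, "poolSizes must be strictly decreasing")
  if (length(object@mspeMean) != k || length(object@mspeSe) != k ||
      length(object@pools) != k)
    msg <- c(msg, "trace components must align")
  if (any(!is.finite(object@mspeMean))) msg <- c(msg, "mspeMean must be finite")
  if (length(msg)) msg else TRUE
})

#' ThresholdResult: the adaptive threshold and the induced feature partition
#'
#' @slot dHat pool size minimising the bootstrap MSPE (ties: smallest size).
#' @slot selected ordered ids of the selected influential set.
#' @slot discarded ids of the noise set.
#' @slot dOneSe smallest pool whose MSPE is within one standard error of the
#'   minimum (the 1-s.e. alternative).
#' @slot mspeAtDHat mean MSPE at the selected size.
#' @exportClass ThresholdResult
setClass("ThresholdResult",
         representation(dHat = "integer", selected = "character",
                        discarded = "character", dOneSe = "integer",
                        mspeAtDHat = "numeric"))

setValidity("ThresholdResult", function(object) {
  msg <- character()
  if (length(object@selected) != object@dHat)
    msg <- c(msg, "selected must contain exactly dHat features")
  if (object@dOneSe > object@dHat)
    msg <- c(msg, "dOneSe cannot exceed dHat")
  if (anyDuplicated(c(object@selected, object@discarded)))
    msg <- c(msg, "selected and discarded must partition the features")
  if (length(msg)) msg else TRUE
})

#' BeIdcResult: full output of one BE-IDC run
#'
#' @slot ranking the [ScreenRanking-class] computed once in Step 1.
#' @slot trace the [EliminationTrace-class] of visited pools.
#' @slot threshold the [ThresholdResult-class].
#' @exportClass BeIdcResult
setClass("BeIdcResult",
         representation(ranking = "ScreenRanking", trace = "EliminationTrace",
                        threshold = "ThresholdResult"))

#' SimulationDesign: parameterisation of one synthetic validation design
#'
#' @slot name one of `"example1"`, `"example2"`, `"example3"`.
#' @slot n,p sample and feature counts.
#' @slot influentialIndices 1-based positions of the truly influential features.
#' @slot coefficients design-specific effect parameters.
#' @slot correlation design-specific correlation parameter.
#' @slot noiseSd standard deviation of the Gaussian noise.
#' @slot seed base seed for the generator.
#' @exportClass SimulationDesign
setClass("SimulationDesign",
         representation(name = "character", n = "integer", p = "integer",
                        influentialIndices = "integer", coefficients = "list",
                        correlation = "numeric", noiseSd = "numeric",
                        seed = "integer"))

setValidity("SimulationDesign", function(object) {
  msg <- character()
  if (!object@name %in% c("example1", "example2", "example3"))
    msg <- c(msg, "unknown design name")
  if (object@n < 2 || object@p < 1) msg <- c(msg, "n and p must be positive")
  if (any(object@influentialIndices < 1 | object@influentialIndices > object@p))
    msg <- c(msg, "influentialIndices must lie in 1..p")
  if (length(msg)) msg else TRUE
})

#' EvaluationReport: replicate-study performance summary
#'
#' @slot averageThreshold mean estimated threshold over replicates.
#' @slot strictPower fraction of replicates selecting every influential feature.
#' @slot individualPower per-influential-feature selection fraction.
#' @slot cvMspe mean 5-fold CV MSPE of the SCAD model on the selected features.
#' @slot nReplicates number of replicates.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
         representation(averageThreshold = "numeric", strictPower = "numeric",
                        individualPower = "numeric", cvMspe = "numeric",
                        nReplicates = "integer"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  pw <- c(object@strictPower, object@individualPower)
  if (any(pw < 0 | pw > 1)) msg <- c(msg, "powers must lie in [0, 1]")
  if (length(object@individualPower) &&
      object@strictPower > min(object@individualPower) + 1e-12)
    msg <- c(msg, "strict power cannot exceed any individual power")
  if (length(msg)) msg else TRUE
})
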