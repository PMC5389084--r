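#' @rdname beidc-accessors
#' @aliases featureMatrix,GenoPheno-method
setMethod("featureMatrix", "GenoPheno", function(object)
  t(SummarizedExperiment::assay(object, "dosage")))

#' @rdname beidc-accessors
setMethod("phenotype", "GenoPheno", function(object) {
  ph <- SummarizedExperiment::colData(object)$phenotype
  if (is.null(ph)) NULL else as.numeric(ph)
})

#' @rdname beidc-accessors
setMethod("featureIds", "GenoPheno", function(object) rownames(object))

#' @rdname beidc-accessors
setMethod("nFeatures", "GenoPheno", function(object) nrow(object))

#' @rdname beidc-accessors
setMethod("nSamples", "GenoPheno", function(object) ncol(object))

#' Genomic coordinates of the features, if any
#' @param object a [GenoPheno-class].
#' @return `data.frame` with `chrom` and `pos`, or NULL when absent.
#' @export
featureCoords <- function(object) {
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chrom", "pos") %in% colnames(rd))) return(NULL)
  data.frame(chrom = as.character(rd$chrom), pos = as.integer(rd$pos),
             row.names = rownames(object))
}

#' @rdname beidc-accessors
setMethod("rankingOrder", "ScreenRanking", function(object) object@order)

#' @rdname beidc-accessors
setMethod("screenScores", "ScreenRanking", function(object) object@scores)

#' @rdname beidc-accessors
setMethod("screenStage", "ScreenRanking", function(object) object@stage)

#' @rdname beidc-accessors
setMethod("rankedFeatures", "ScreenRanking", function(object)
  object@featureIds[object@order])

#' @rdname beidc-accessors
setMethod("featureIds", "ScreenRanking", function(object) object@featureIds)

#' @rdname beidc-accessors
setMethod("dHat", "ThresholdResult", function(object) object@dHat)

#' @rdname beidc-accessors
setMethod("dOneSe", "ThresholdResult", function(object) object@dOneSe)

#' @rdname beidc-accessors
setMethod("selectedFeatures", "ThresholdResult", function(object) object@selected)

#' @rdname beidc-accessors
setMethod("discardedFeatures", "ThresholdResult", function(object) object@discarded)

#' @rdname beidc-accessors
setMethod("poolSizes", "EliminationTrace", function(object) object@poolSizes)

#' @rdname beidc-accessors
setMethod("mspeMean", "EliminationTrace", function(object) object@mspeMean)

#' @rdname beidc-accessors
setMethod("mspeSe", "EliminationTrace", function(object) object@mspeSe)

#' @rdname beidc-accessors
setMethod("screenRanking", "BeIdcResult", function(object) object@ranking)

#' @rdname beidc-accessors
setMethod("eliminationTrace", "BeIdcResult", function(object) object@trace)

#' @rdname beidc-accessors
setMethod("thresholdResult", "BeIdcResult", function(object) object@threshold)

#' @rdname beidc-accessors
setMethod("dHat", "BeIdcResult", function(object) object@threshold@dHat)

#' @rdname beidc-accessors
setMethod("selectedFeatures", "BeIdcResult", function(object)
  object@threshold@selected)

#' Coefficient accessors for ScadFit
#' @param object a [ScadFit-class].
#' @return `coef`: named numeric with `(Intercept)` first.
#' @export
setMethod("coef", "ScadFit", function(object, ...) {
  c("(Intercept)" = object@intercept, object@beta)
})

#' Predict from a ScadFit
#' @param object a [ScadFit-class].
#' @param newdata numeric matrix with the same columns the fit was trained on.
#' @param ... ignored.
#' @return numeric vector of predictions.
#' @export
setMethod("predict", "ScadFit", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object@beta) + object@intercept
})

#' @describeIn ScreenRanking-class tabular view: one row per rank.
#' @param x a `ScreenRanking` or `EliminationTrace`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ScreenRanking", function(x, ...) {
  data.frame(feature_id = x@featureIds[x@order],
             score = x@scores[x@order],
             rank = seq_along(x@order),
             stage = x@stage[x@order],
             row.names = NULL)
})

#' @describeIn EliminationTrace-class tabular view: one row per visited pool.
#' @param x an `EliminationTrace`.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "EliminationTrace", function(x, ...) {
  data.frame(pool_size = x@poolSizes, mspe_mean = x@mspeMean,
             mspe_se = x@mspeSe, row.names = NULL)
})

setMethod("show", "ScreenRanking", function(object) {
  p <- length(object@order)
  cat("ScreenRanking with", p, "features,",
      length(unique(object@stage)), "stage(s)\n")
  top <- utils::head(object@featureIds[object@order], 5L)
  cat("  top:", paste(top, collapse = ", "),
      if (p > 5) "..." else "", "\n")
})

setMethod("show", "EliminationTrace", function(object) {
  cat("EliminationTrace over", length(object@poolSizes), "pool sizes (",
      object@poolSizes[1], "->", utils::tail(object@poolSizes, 1), ")\n")
  i <- which.min(object@mspeMean)
  cat("  min MSPE", format(object@mspeMean[i], digits = 4),
      "at pool size", object@poolSizes[i], "\n")
})

setMethod("show", "ThresholdResult", function(object) {
  cat("ThresholdResult: d-hat =", object@dHat,
      "(1-s.e. alternative:", object@dOneSe, ")\n")
  cat("  MSPE at d-hat:", format(object@mspeAtDHat, digits = 4), "\n")
  cat("  selected:", paste(utils::head(object@selected, 8L), collapse = ", "),
      if (object@dHat > 8) "..." else "", "\n")
})

setMethod("show", "BeIdcResult", function(object) {
  cat("BeIdcResult\n")
  show(object@threshold)
})

setMethod("show", "ScadFit", function(object) {
  cat("ScadFit: lambda =", format(object@lambdaSelected, digits = 4),
      "|", length(object@nonzeroIndexSet), "nonzero coefficient(s)\n")
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport over", object@nReplicates, "replicates\n")
  cat("  average threshold:", format(object@averageThreshold, digits = 4), "\n")
  cat("  strict power:", format(object@strictPower, digits = 3), "\n")
  if (is.finite(object@cvMspe))
    cat("  CV MSPE:", format(object@cvMspe, digits = 4), "\n")
})
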