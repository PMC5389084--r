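#' @name beidc-generics
#' @title Generics for screening and elimination
#' @description S4 generics dispatched on either plain matrices or
#'   [GenoPheno-class] containers.
#' @param x feature matrix (samples by features) or a [GenoPheno-class].
#' @param y numeric phenotype (omitted for `GenoPheno`, which carries its own).
#' @param schedule an [IterationSchedule-class].
#' @param config a [BeConfig-class].
#' @param ... passed to methods.
NULL

#' @rdname beidc-generics
#' @export
setGeneric("dcsisRank", function(x, y, ...) standardGeneric("dcsisRank"))

#' @rdname beidc-generics
#' @export
setGeneric("idcsisRank", function(x, y, schedule = iterationSchedule(), ...)
  standardGeneric("idcsisRank"))

#' @rdname beidc-generics
#' @export
setGeneric("runBeIdc", function(x, y, config = beConfig(),
                                schedule = iterationSchedule(), ...)
  standardGeneric("runBeIdc"))

#' @name beidc-accessors
#' @title Accessors for beidc S4 objects
#' @param object a beidc S4 object.
#' @description Slot accessors; user code should prefer these over `@`.
NULL

#' @rdname beidc-accessors
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname beidc-accessors
#' @export
setGeneric("phenotype", function(object) standardGeneric("phenotype"))

#' @rdname beidc-accessors
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname beidc-accessors
#' @export
setGeneric("nFeatures", function(object) standardGeneric("nFeatures"))

#' @rdname beidc-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname beidc-accessors
#' @export
setGeneric("rankingOrder", function(object) standardGeneric("rankingOrder"))

#' @rdname beidc-accessors
#' @export
setGeneric("screenScores", function(object) standardGeneric("screenScores"))

#' @rdname beidc-accessors
#' @export
setGeneric("screenStage", function(object) standardGeneric("screenStage"))

#' @rdname beidc-accessors
#' @export
setGeneric("rankedFeatures", function(object) standardGeneric("rankedFeatures"))

#' @rdname beidc-accessors
#' @export
setGeneric("dHat", function(object) standardGeneric("dHat"))

#' @rdname beidc-accessors
#' @export
setGeneric("dOneSe", function(object) standardGeneric("dOneSe"))

#' @rdname beidc-accessors
#' @export
setGeneric("selectedFeatures", function(object) standardGeneric("selectedFeatures"))

#' @rdname beidc-accessors
#' @export
setGeneric("discardedFeatures", function(object) standardGeneric("discardedFeatures"))

#' @rdname beidc-accessors
#' @export
setGeneric("poolSizes", function(object) standardGeneric("poolSizes"))

#' @rdname beidc-accessors
#' @export
setGeneric("mspeMean", function(object) standardGeneric("mspeMean"))

#' @rdname beidc-accessors
#' @export
setGeneric("mspeSe", function(object) standardGeneric("mspeSe"))

#' @rdname beidc-accessors
#' @export
setGeneric("screenRanking", function(object) standardGeneric("screenRanking"))

#' @rdname beidc-accessors
#' @export
setGeneric("eliminationTrace", function(object) standardGeneric("eliminationTrace"))

#' @rdname beidc-accessors
#' @export
setGeneric("thresholdResult", function(object) standardGeneric("thresholdResult"))
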