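## Accessor generics for the package's S4 classes. Slot access from user
## code should go through these.

#' @rdname RoiTimeSeries
#' @param object An object of the documented class.
#' @export
setGeneric("seriesData", function(object) standardGeneric("seriesData"))
#' @rdname RoiTimeSeries
#' @export
setMethod("seriesData", "RoiTimeSeries", function(object) object@data)

#' @rdname RoiTimeSeries
#' @export
setGeneric("trSeconds", function(object) standardGeneric("trSeconds"))
#' @rdname RoiTimeSeries
#' @export
setMethod("trSeconds", "RoiTimeSeries", function(object) object@trSeconds)

#' @rdname RoiTimeSeries
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname RoiTimeSeries
#' @export
setMethod("subjectId", "RoiTimeSeries", function(object) object@subjectId)

#' @rdname RoiTimeSeries
#' @export
setGeneric("roiNames", function(object) standardGeneric("roiNames"))
#' @rdname RoiTimeSeries
#' @export
setMethod("roiNames", "RoiTimeSeries", function(object) object@roiNames)

#' @rdname RoiTimeSeries
#' @export
setGeneric("nTimepoints", function(object) standardGeneric("nTimepoints"))
#' @rdname RoiTimeSeries
#' @export
setMethod("nTimepoints", "RoiTimeSeries", function(object) nrow(object@data))

#' @rdname RoiTimeSeries
#' @export
setGeneric("nRois", function(object) standardGeneric("nRois"))
#' @rdname RoiTimeSeries
#' @export
setMethod("nRois", "RoiTimeSeries", function(object) ncol(object@data))

#' @rdname EcStack-class
#' @param object An EcStack.
#' @export
setGeneric("ecMatrices", function(object) standardGeneric("ecMatrices"))
#' @rdname EcStack-class
#' @export
setMethod("ecMatrices", "EcStack", function(object) object@matrices)

#' @rdname EcStack-class
#' @export
setGeneric("supportMask", function(object) standardGeneric("supportMask"))
#' @rdname EcStack-class
#' @export
setMethod("supportMask", "EcStack", function(object) object@supportMask)

#' @rdname EcStack-class
#' @export
setGeneric("ecAlpha", function(object) standardGeneric("ecAlpha"))
#' @rdname EcStack-class
#' @export
setMethod("ecAlpha", "EcStack", function(object) object@alpha)

#' @rdname FcMatrix-class
#' @param object An FcMatrix.
#' @export
setGeneric("fcMatrix", function(object) standardGeneric("fcMatrix"))
#' @rdname FcMatrix-class
#' @export
setMethod("fcMatrix", "FcMatrix", function(object) object@matrix)

#' @rdname SelectorModel-class
#' @param object A SelectorModel.
#' @export
setGeneric("selectedIndices",
           function(object) standardGeneric("selectedIndices"))
#' @rdname SelectorModel-class
#' @export
setMethod("selectedIndices", "SelectorModel",
          function(object) object@selectedIndices)

#' @rdname SelectorModel-class
#' @export
setGeneric("selectorLambda",
           function(object) standardGeneric("selectorLambda"))
#' @rdname SelectorModel-class
#' @export
setMethod("selectorLambda", "SelectorModel", function(object) object@lambda)

#' @rdname SelectorModel-class
#' @export
setGeneric("selectorCoefficients",
           function(object) standardGeneric("selectorCoefficients"))
#' @rdname SelectorModel-class
#' @export
setMethod("selectorCoefficients", "SelectorModel",
          function(object) object@coefficients)

#' @rdname PopulationGraph-class
#' @param object A PopulationGraph.
#' @export
setGeneric("adjacency", function(object) standardGeneric("adjacency"))
#' @rdname PopulationGraph-class
#' @export
setMethod("adjacency", "PopulationGraph", function(object) object@adjacency)

#' @rdname PopulationGraph-class
#' @export
setGeneric("graphPhenotypes",
           function(object) standardGeneric("graphPhenotypes"))
#' @rdname PopulationGraph-class
#' @export
setMethod("graphPhenotypes", "PopulationGraph",
          function(object) object@phenotypes)

#' @rdname SpectralOperator-class
#' @param object A SpectralOperator.
#' @export
setGeneric("normalizedLaplacian",
           function(object) standardGeneric("normalizedLaplacian"))
#' @rdname SpectralOperator-class
#' @export
setMethod("normalizedLaplacian", "SpectralOperator",
          function(object) object@laplacianNormalized)

#' @rdname SpectralOperator-class
#' @export
setGeneric("scaledLaplacian",
           function(object) standardGeneric("scaledLaplacian"))
#' @rdname SpectralOperator-class
#' @export
setMethod("scaledLaplacian", "SpectralOperator",
          function(object) object@laplacianScaled)

#' @rdname SpectralOperator-class
#' @export
setGeneric("lambdaMax", function(object) standardGeneric("lambdaMax"))
#' @rdname SpectralOperator-class
#' @export
setMethod("lambdaMax", "SpectralOperator", function(object) object@lambdaMax)

#' @rdname RelevanceReport-class
#' @param object A RelevanceReport.
#' @export
setGeneric("meanScores", function(object) standardGeneric("meanScores"))
#' @rdname RelevanceReport-class
#' @export
setMethod("meanScores", "RelevanceReport", function(object) object@meanScores)

#' @rdname RelevanceReport-class
#' @export
setGeneric("selectedConnections",
           function(object) standardGeneric("selectedConnections"))
#' @rdname RelevanceReport-class
#' @export
setMethod("selectedConnections", "RelevanceReport",
          function(object) object@selected)

#' @rdname RelevanceReport-class
#' @export
setGeneric("relevanceThreshold",
           function(object) standardGeneric("relevanceThreshold"))
#' @rdname RelevanceReport-class
#' @export
setMethod("relevanceThreshold", "RelevanceReport",
          function(object) object@threshold)
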