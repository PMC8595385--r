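#' @rdname FeatureTable-accessors
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("featureIDs", function(object) standardGeneric("featureIDs"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("sampleIDs", function(object) standardGeneric("sampleIDs"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("taxonomy", function(object) standardGeneric("taxonomy"))

#' @rdname FeatureTable-accessors
#' @export
setGeneric("taxonomy<-", function(object, value) standardGeneric("taxonomy<-"))

#' @rdname RarefiedEnsemble-accessors
#' @export
setGeneric("rarefactionDepth", function(object) standardGeneric("rarefactionDepth"))

#' @rdname RarefiedEnsemble-accessors
#' @export
setGeneric("samplingMode", function(object) standardGeneric("samplingMode"))

#' @rdname RarefiedEnsemble-accessors
#' @export
setGeneric("nReps", function(object) standardGeneric("nReps"))

#' @rdname RarefiedEnsemble-accessors
#' @export
setGeneric("droppedSamples", function(object) standardGeneric("droppedSamples"))
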