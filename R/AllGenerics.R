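#' @rdname OmicsView-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("viewName", function(x) standardGeneric("viewName"))

#' @rdname OmicsView-class
#' @export
setGeneric("viewMatrix", function(x) standardGeneric("viewMatrix"))

#' @rdname OmicsView-class
#' @export
setGeneric("lossWeight", function(x) standardGeneric("lossWeight"))

#' @rdname OmicsView-class
#' @param value replacement value.
#' @export
setGeneric("lossWeight<-", function(x, value) standardGeneric("lossWeight<-"))

#' @rdname OmicsView-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OmicsView-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname LatentFeatures-class
#' @param x a [LatentFeatures-class] object.
#' @export
setGeneric("latentMatrix", function(x) standardGeneric("latentMatrix"))

#' @rdname SimilarityBundle-class
#' @param x a [SimilarityBundle-class] object.
#' @export
setGeneric("fusedMatrix", function(x) standardGeneric("fusedMatrix"))

#' @rdname PatientGraph-class
#' @param x a [PatientGraph-class] object.
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname PatientGraph-class
#' @export
setGeneric("normalizedAdjacency", function(x) standardGeneric("normalizedAdjacency"))

#' @rdname MetricsReport-class
#' @param x a [MetricsReport-class] object.
#' @export
setGeneric("perFoldMetrics", function(x) standardGeneric("perFoldMetrics"))

#' @rdname MetricsReport-class
#' @export
setGeneric("aggregateMetrics", function(x) standardGeneric("aggregateMetrics"))

#' @rdname MetricsReport-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))
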