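#' @rdname OmicsView-class
#' @export
setMethod("viewName", "OmicsView", function(x) x@name)

#' @rdname OmicsView-class
#' @export
setMethod("viewMatrix", "OmicsView", function(x) x@matrix)

#' @rdname OmicsView-class
#' @export
setMethod("lossWeight", "OmicsView", function(x) x@lossWeight)

#' @rdname OmicsView-class
#' @export
setReplaceMethod("lossWeight", "OmicsView", function(x, value) {
  x@lossWeight <- value
  validObject(x)
  x
})

#' @rdname OmicsView-class
#' @export
setMethod("sampleIds", "OmicsView", function(x) rownames(x@matrix))

#' @rdname OmicsView-class
#' @export
setMethod("featureIds", "OmicsView", function(x) colnames(x@matrix))

#' @rdname OmicsView-class
#' @export
setMethod("dim", "OmicsView", function(x) dim(x@matrix))

setMethod("show", "OmicsView", function(object) {
  cat(sprintf("OmicsView '%s': %d samples x %d features (loss weight %.3g)\n",
              object@name, nrow(object@matrix), ncol(object@matrix),
              object@lossWeight))
  nmiss <- sum(is.na(object@matrix))
  if (nmiss > 0) cat(sprintf("  %d missing cells\n", nmiss))
})

#' @rdname LatentFeatures-class
#' @export
setMethod("latentMatrix", "LatentFeatures", function(x) x@matrix)

#' @rdname LatentFeatures-class
#' @export
setMethod("sampleIds", "LatentFeatures", function(x) rownames(x@matrix))

#' @rdname LatentFeatures-class
#' @export
setMethod("dim", "LatentFeatures", function(x) dim(x@matrix))

setMethod("show", "LatentFeatures", function(object) {
  cat(sprintf("LatentFeatures: %d samples x %d latent dimensions\n",
              nrow(object@matrix), ncol(object@matrix)))
})

#' @rdname SimilarityBundle-class
#' @export
setMethod("fusedMatrix", "SimilarityBundle", function(x) x@fused)

setMethod("show", "SimilarityBundle", function(object) {
  cat(sprintf("SimilarityBundle: %d views, %d samples (mu = %.3g, K = %d)\n",
              length(object@W), nrow(object@fused),
              object@params$mu, object@params$K))
})

#' @rdname PatientGraph-class
#' @export
setMethod("adjacency", "PatientGraph", function(x) x@adjacency)

#' @rdname PatientGraph-class
#' @export
setMethod("normalizedAdjacency", "PatientGraph", function(x) x@normalized)

#' @rdname PatientGraph-class
#' @export
setMethod("sampleIds", "PatientGraph", function(x) rownames(x@adjacency))

setMethod("show", "PatientGraph", function(object) {
  n <- nrow(object@adjacency)
  ne <- sum(object@adjacency) / 2
  cat(sprintf("PatientGraph: %d patients, %d edges (density %.3f)\n",
              n, ne, if (n > 1) ne / (n * (n - 1) / 2) else 0))
})

setMethod("show", "RRGCNFit", function(object) {
  dims <- object@config$layerDims
  cat(sprintf("RRGCNFit: GCN layers (%s), %d epochs, final loss %.4g\n",
              paste(dims, collapse = ", "), length(object@lossTrace),
              if (length(object@lossTrace)) tail(object@lossTrace, 1) else NA))
})

#' @rdname MetricsReport-class
#' @export
setMethod("perFoldMetrics", "MetricsReport", function(x) x@perFold)

#' @rdname MetricsReport-class
#' @export
setMethod("aggregateMetrics", "MetricsReport", function(x) x@aggregate)

#' @rdname MetricsReport-class
#' @export
setMethod("perClassMetrics", "MetricsReport", function(x) x@perClass)

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: %d repeat(s) x %d fold(s)\n",
              object@nRepeats, object@nFolds))
  agg <- object@aggregate
  cat("  ", paste(sprintf("%s = %.4f", names(agg), agg), collapse = ", "),
      "\n", sep = "")
})
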