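#' @import methods
#' @importFrom stats rnorm runif median cor sd quantile predict
#' @importFrom utils head tail
NULL

#' OmicsView: one omics data view
#'
#' A single samples-by-features matrix for one omics data type (for example
#' transcriptome expression, copy-number values, or somatic-mutation
#' features), together with a view name and the weight its reconstruction
#' error receives in the autoencoder loss. Sample identifiers are the row
#' names and feature identifiers the column names; duplicated feature names
#' are permitted before preprocessing (they are resolved by
#' \code{\link{resolveDuplicateFeatures}}).
#'
#' @slot name single string naming the view (e.g. \code{"mrna"}).
#' @slot matrix numeric samples-by-features matrix; \code{NA} marks missing
#'   cells. Row names (sample ids) must be unique; column names are the
#'   feature ids.
#' @slot lossWeight reconstruction-loss weight in \[0, 1\] (the per-view
#'   coefficient of the weighted autoencoder loss; weights across views sum
#'   to 1).
#'
#' @seealso [omicsView()], [preprocessView()], [trainAutoencoder()]
#' @export
setClass("OmicsView",
  representation(name = "character", matrix = "matrix", lossWeight = "numeric"),
  prototype(name = "view", matrix = matrix(numeric(0), 0, 0), lossWeight = 1)
)

setValidity("OmicsView", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  m <- object@matrix
  if (!is.numeric(m)) msg <- c(msg, "'matrix' must be numeric")
  if (is.null(rownames(m)) && nrow(m) > 0)
    msg <- c(msg, "'matrix' must have row names (sample ids)")
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m)))
    msg <- c(msg, "sample ids (row names) must be unique")
  if (is.null(colnames(m)) && ncol(m) > 0)
    msg <- c(msg, "'matrix' must have column names (feature ids)")
  if (length(object@lossWeight) != 1L || is.na(object@lossWeight) ||
      object@lossWeight < 0 || object@lossWeight > 1)
    msg <- c(msg, "'lossWeight' must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsView
#'
#' @param name view name.
#' @param matrix numeric samples-by-features matrix with sample ids as row
#'   names and feature ids as column names.
#' @param lossWeight per-view autoencoder loss weight in \[0, 1\].
#' @return An [OmicsView-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("S", 1:3), paste0("g", 1:4)))
#' omicsView("mrna", m, lossWeight = 0.4)
#' @export
omicsView <- function(name, matrix, lossWeight = 1) {
  new("OmicsView", name = name, matrix = matrix, lossWeight = lossWeight)
}

#' CohortSpec: design of a synthetic multi-omics cohort
#'
#' Describes a cohort with a known subtype partition shared by all views.
#' Each view carries Gaussian noise plus class-specific mean shifts on a
#' disjoint block of informative features per class, so class separability is
#' fully controlled by \code{effectSize}. A fraction of cells can be set
#' missing (\code{NA}) or zeroed to exercise the preprocessing filters.
#'
#' @slot nSamples total number of samples.
#' @slot classSizes integer vector of per-class sample counts; must sum to
#'   \code{nSamples}. Classes are labelled \code{0 .. k-1} in this order.
#' @slot views list of per-view descriptions, each a list with elements
#'   \code{name}, \code{nFeatures}, \code{nInformative} (informative features
#'   are split into per-class blocks) and optionally \code{classes}, the
#'   integer labels of the classes this view can discriminate (defaults to
#'   all classes).
#' @slot effectSize mean shift of informative features for their class, in
#'   units of \code{noiseSd}.
#' @slot noiseSd standard deviation of the Gaussian noise.
#' @slot missingRate fraction of cells set to \code{NA}, in \[0, 1).
#' @slot zeroRate fraction of cells set to 0, in \[0, 1).
#' @slot seed integer seed; generation is deterministic given the spec.
#' @seealso [cohortSpec()], [generateCohort()]
#' @export
setClass("CohortSpec",
  representation(nSamples = "integer", classSizes = "integer", views = "list",
                 effectSize = "numeric", noiseSd = "numeric",
                 missingRate = "numeric", zeroRate = "numeric", seed = "integer")
)

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (length(object@nSamples) != 1L || object@nSamples < 1L)
    msg <- c(msg, "'nSamples' must be a single positive integer")
  if (any(object@classSizes < 1L))
    msg <- c(msg, "'classSizes' must all be positive")
  if (sum(object@classSizes) != object@nSamples)
    msg <- c(msg, sprintf("'classSizes' must sum to 'nSamples' (%d != %d)",
                          sum(object@classSizes), object@nSamples))
  if (length(object@views) == 0L)
    msg <- c(msg, "'views' must contain at least one view")
  for (v in object@views) {
    if (!all(c("name", "nFeatures", "nInformative") %in% names(v))) {
      msg <- c(msg, "each view needs 'name', 'nFeatures', 'nInformative'")
      next
    }
    if (v$nInformative > v$nFeatures)
      msg <- c(msg, sprintf("view '%s': 'nInformative' (%d) exceeds 'nFeatures' (%d)",
                            v$name, v$nInformative, v$nFeatures))
    if (!is.null(v$classes) &&
        !all(v$classes %in% (seq_along(object@classSizes) - 1L)))
      msg <- c(msg, sprintf("view '%s': 'classes' outside 0..%d",
                            v$name, length(object@classSizes) - 1L))
  }
  if (object@effectSize < 0) msg <- c(msg, "'effectSize' must be nonnegative")
  if (object@noiseSd <= 0) msg <- c(msg, "'noiseSd' must be positive")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "'missingRate' must lie in [0, 1)")
  if (object@zeroRate < 0 || object@zeroRate >= 1)
    msg <- c(msg, "'zeroRate' must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' LatentFeatures: low-dimensional sample embedding
#'
#' The samples-by-d matrix of middle-hidden-layer activations produced by the
#' trained autoencoder. This matrix is the node-feature matrix X of the graph
#' convolutional classifier.
#'
#' @slot matrix numeric samples-by-d matrix with sample ids as row names; no
#'   missing values.
#' @seealso [trainAutoencoder()], [trainRRGCN()]
#' @export
setClass("LatentFeatures", representation(matrix = "matrix"))

setValidity("LatentFeatures", function(object) {
  msg <- character(0)
  if (anyNA(object@matrix)) msg <- c(msg, "latent matrix must not contain NA")
  if (is.null(rownames(object@matrix)) && nrow(object@matrix) > 0)
    msg <- c(msg, "latent matrix must carry sample ids as row names")
  if (length(msg)) msg else TRUE
})

#' SimilarityBundle: per-view and fused patient similarity matrices
#'
#' Holds, for each omics view, the scaled-exponential similarity kernel W,
#' its full normalization P (diagonal 1/2, unit row sums), and the
#' k-nearest-neighbour affinity S (row-stochastic over at most K supports),
#' together with the cross-diffusion fused network and the kernel parameters.
#'
#' @slot W list of n-by-n symmetric nonnegative kernel matrices.
#' @slot P list of n-by-n row-stochastic matrices with diagonal 1/2.
#' @slot S list of n-by-n row-stochastic kNN affinity matrices.
#' @slot fused n-by-n symmetric fused similarity matrix.
#' @slot params list with \code{mu} (kernel scaling factor), \code{K}
#'   (neighbourhood size) and \code{iterations} (fusion rounds performed).
#' @seealso [buildSimilarityBundle()], [snfFuse()]
#' @export
setClass("SimilarityBundle",
  representation(W = "list", P = "list", S = "list", fused = "matrix",
                 params = "list")
)

setValidity("SimilarityBundle", function(object) {
  msg <- character(0)
  for (W in object@W) {
    if (any(W < 0)) { msg <- c(msg, "kernel matrices must be nonnegative"); break }
    if (max(abs(W - t(W))) > 1e-8) { msg <- c(msg, "kernel matrices must be symmetric"); break }
  }
  for (P in object@P)
    if (max(abs(rowSums(P) - 1)) > 1e-6) {
      msg <- c(msg, "P matrices must be row-stochastic"); break
    }
  if (length(object@fused) &&
      max(abs(object@fused - t(object@fused))) > 1e-8)
    msg <- c(msg, "fused matrix must be symmetric")
  if (length(msg)) msg else TRUE
})

#' PatientGraph: binary patient similarity graph
#'
#' The patient graph used by the graph convolutional classifier: a binary
#' adjacency matrix A (symmetric, zero diagonal) whose edges join patient
#' pairs whose similarity profiles correlate above the Pearson threshold, and
#' the renormalized propagation matrix
#' \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}} with
#' \eqn{\tilde A = A + I}.
#'
#' @slot adjacency n-by-n binary matrix, symmetric with zero diagonal.
#' @slot normalized n-by-n symmetric propagation matrix.
#' @seealso [buildPatientGraph()], [pearsonAdjacency()], [normalizeAdjacency()]
#' @export
setClass("PatientGraph",
  representation(adjacency = "matrix", normalized = "matrix")
)

setValidity("PatientGraph", function(object) {
  A <- object@adjacency
  msg <- character(0)
  if (nrow(A) != ncol(A)) msg <- c(msg, "adjacency must be square")
  if (length(A)) {
    if (!all(A %in% c(0, 1))) msg <- c(msg, "adjacency must be binary")
    if (any(diag(A) != 0)) msg <- c(msg, "adjacency diagonal must be zero")
    if (!isTRUE(all.equal(A, t(A)))) msg <- c(msg, "adjacency must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' RRGCNFit: a trained residual graph convolutional classifier
#'
#' @slot params list of weight matrices and biases of the four graph
#'   convolution layers and the two skip-connection linear projections.
#' @slot lossTrace numeric vector of per-epoch masked training loss.
#' @slot probabilities n-by-k matrix of softmax class probabilities for all
#'   nodes in the graph (rows sum to 1).
#' @slot config the [rrgcnConfig()] list used for training.
#' @seealso [trainRRGCN()], [rrgcnForward()]
#' @export
setClass("RRGCNFit",
  representation(params = "list", lossTrace = "numeric",
                 probabilities = "matrix", config = "list")
)

#' MetricsReport: cross-validation performance report
#'
#' @slot perFold data.frame with one row per (repeat, fold) and columns
#'   \code{repeat_}, \code{fold}, \code{precision}, \code{recall}, \code{f1},
#'   \code{accuracy}, \code{auc}, \code{pr_auc}.
#' @slot aggregate named numeric vector: the arithmetic mean of each metric
#'   over all folds.
#' @slot perClass data.frame of one-vs-rest per-class metrics averaged over
#'   folds.
#' @slot nRepeats number of cross-validation repetitions.
#' @slot nFolds number of folds per repetition.
#' @seealso [repeatedStratifiedCV()], [classificationMetrics()]
#' @export
setClass("MetricsReport",
  representation(perFold = "data.frame", aggregate = "numeric",
                 perClass = "data.frame", nRepeats = "integer",
                 nFolds = "integer")
)

setValidity("MetricsReport", function(object) {
  msg <- character(0)
  agg <- object@aggregate
  ok <- is.na(agg) | (agg >= 0 & agg <= 1)
  if (!all(ok)) msg <- c(msg, "aggregate metrics must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
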