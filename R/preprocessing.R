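#' Remove features that carry no signal in any sample
#'
#' Drops every feature whose value is zero or missing in all samples: this
#' covers features absent from every sample (all `NA`), features at zero in
#' every sample, and mixtures of the two. The order of surviving features and
#' the sample set are unchanged.
#'
#' @param view an [OmicsView-class].
#' @return The filtered view.
#' @examples
#' m <- cbind(a = c(1, 2, 3), b = c(0, 0, 0), c = c(0, NA, 0))
#' rownames(m) <- paste0("S", 1:3)
#' featureIds(dropDeadFeatures(omicsView("x", m)))  # "a"
#' @export
dropDeadFeatures <- function(view) {
  m <- viewMatrix(view)
  dead <- apply(m, 2L, function(x) all(is.na(x) | x == 0))
  if (all(dead))
    stop("view '", viewName(view),
         "': every feature is zero or missing in all samples; nothing left")
  out <- m[, !dead, drop = FALSE]
  omicsView(viewName(view), out, lossWeight = lossWeight(view))
}

#' Resolve duplicated feature identifiers
#'
#' For each feature id occurring more than once (e.g. a gene measured by
#' several probes), exactly one column is kept: the one whose mean value
#' across samples has the smallest absolute value, ties broken by first
#' occurrence. Means are computed on the matrix as read (before any log
#' transform), ignoring missing cells. Column order of the kept columns is
#' preserved.
#'
#' @param view an [OmicsView-class].
#' @return View with unique feature ids.
#' @export
resolveDuplicateFeatures <- function(view) {
  m <- viewMatrix(view)
  ids <- colnames(m)
  if (!anyDuplicated(ids)) return(view)
  mu <- abs(colMeans(m, na.rm = TRUE))
  keep <- rep(TRUE, ncol(m))
  for (id in unique(ids[duplicated(ids)])) {
    cols <- which(ids == id)
    best <- cols[which.min(mu[cols])]   # which.min takes the first minimum
    keep[setdiff(cols, best)] <- FALSE
  }
  omicsView(viewName(view), m[, keep, drop = FALSE],
            lossWeight = lossWeight(view))
}

#' Log-transform an expression view
#'
#' Replaces every value v by `log2(v + 0.1)`. Intended only for expression
#' data on the raw FPKM scale; all values must be nonnegative.
#'
#' @param view an [OmicsView-class] with nonnegative values.
#' @return The transformed view.
#' @examples
#' m <- matrix(c(0, 0.9, 7.9, 1.9), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("g1", "g2")))
#' viewMatrix(logTransformExpression(omicsView("mrna", m)))
#' @export
logTransformExpression <- function(view) {
  m <- viewMatrix(view)
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0)
    stop(sprintf(
      "view '%s': negative value %.6g at sample '%s', feature '%s'; log2(FPKM + 0.1) needs nonnegative input",
      viewName(view), m[neg[1, 1], neg[1, 2]],
      rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
  omicsView(viewName(view), log2(m + 0.1), lossWeight = lossWeight(view))
}

#' Impute isolated missing cells with the feature median
#'
#' @param view an [OmicsView-class]; no feature may be entirely missing
#'   (run [dropDeadFeatures()] first).
#' @return View without missing values.
#' @export
imputeMissing <- function(view) {
  m <- viewMatrix(view)
  if (!anyNA(m)) return(view)
  for (j in which(colSums(is.na(m)) > 0)) {
    med <- median(m[, j], na.rm = TRUE)
    if (is.na(med))
      stop("view '", viewName(view), "': feature '", colnames(m)[j],
           "' is entirely missing; drop dead features first")
    m[is.na(m[, j]), j] <- med
  }
  omicsView(viewName(view), m, lossWeight = lossWeight(view))
}

#' Clean one omics view
#'
#' Applies the full cleaning pipeline: dead-feature removal, duplicate
#' resolution (smallest |mean| wins, computed on the scale as read), an
#' optional `log2(v + 0.1)` transform for raw FPKM expression data, and
#' feature-median imputation of the remaining isolated missing cells. The
#' cleaning steps are idempotent; the log transform is a one-time scale
#' change and is off by default.
#'
#' @param view an [OmicsView-class].
#' @param logTransform apply [logTransformExpression()] (expression views on
#'   the raw FPKM scale only).
#' @return The cleaned view: unique feature ids, no dead features, no
#'   missing values, samples untouched and in the original order.
#' @export
preprocessView <- function(view, logTransform = FALSE) {
  out <- dropDeadFeatures(view)
  out <- resolveDuplicateFeatures(out)
  if (logTransform) out <- logTransformExpression(out)
  imputeMissing(out)
}
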