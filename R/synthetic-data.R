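#' Describe a synthetic multi-omics cohort
#'
#' Builds a [CohortSpec-class] for the synthetic cohort generator. The
#' defaults emulate the structure of a four-subtype gastric-cancer cohort:
#' 272 samples with class sizes 25/60/51/136 (the EBV/MSI/GS/CIN imbalance)
#' and three omics views sharing the same subtype partition. Feature counts
#' are kept at desk scale (hundreds per view rather than the tens of
#' thousands of a real TCGA export); the informative features of each view
#' are split into disjoint per-class blocks so that which classes a view can
#' discriminate is fully controlled.
#'
#' @param nSamples total cohort size; defaults to `sum(classSizes)`.
#' @param classSizes per-class sample counts; classes are coded
#'   `0 .. length(classSizes) - 1`.
#' @param views list of view descriptions: each a list with `name`,
#'   `nFeatures`, `nInformative`, and optionally `classes` (integer labels of
#'   the classes whose samples are mean-shifted in this view; default all).
#' @param effectSize mean shift of a class's informative features, in units
#'   of `noiseSd`. 0 gives a cohort with no class signal.
#' @param noiseSd standard deviation of the Gaussian noise floor.
#' @param missingRate fraction of cells set to `NA` ("absent" measurements).
#' @param zeroRate fraction of cells set to exactly 0 (exercises the
#'   dead-feature filter).
#' @param seed integer seed for deterministic generation.
#' @return A validated [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(effectSize = 4, seed = 7)
#' spec
#' @export
cohortSpec <- function(nSamples = NULL,
                       classSizes = c(25L, 60L, 51L, 136L),
                       views = list(
                         list(name = "mrna",    nFeatures = 300L, nInformative = 60L),
                         list(name = "cnv",     nFeatures = 200L, nInformative = 40L),
                         list(name = "somatic", nFeatures = 100L, nInformative = 20L)),
                       effectSize = 1, noiseSd = 1,
                       missingRate = 0.01, zeroRate = 0.02, seed = 1L) {
  classSizes <- as.integer(classSizes)
  if (is.null(nSamples)) nSamples <- sum(classSizes)
  views <- lapply(views, function(v) {
    v$nFeatures <- as.integer(v$nFeatures)
    v$nInformative <- as.integer(v$nInformative)
    if (!is.null(v$classes)) v$classes <- as.integer(v$classes)
    v
  })
  new("CohortSpec", nSamples = as.integer(nSamples), classSizes = classSizes,
      views = views, effectSize = as.numeric(effectSize),
      noiseSd = as.numeric(noiseSd), missingRate = as.numeric(missingRate),
      zeroRate = as.numeric(zeroRate), seed = as.integer(seed))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d samples, %d classes (%s), %d views\n",
              object@nSamples, length(object@classSizes),
              paste(object@classSizes, collapse = "/"), length(object@views)))
  for (v in object@views)
    cat(sprintf("  view '%s': %d features (%d informative)\n",
                v$name, v$nFeatures, v$nInformative))
  cat(sprintf("  effect size %.3g (in noise-SD units), noise SD %.3g, missing %.3g, zeros %.3g, seed %d\n",
              object@effectSize, object@noiseSd, object@missingRate,
              object@zeroRate, object@seed))
})

#' Generate a synthetic multi-omics cohort with known subtype structure
#'
#' Each view is drawn as Gaussian noise `N(0, noiseSd^2)`; the `nInformative`
#' features of a view are divided into disjoint blocks, one block per class
#' the view discriminates, and samples of a class receive a mean shift of
#' `effectSize * noiseSd` on their block. A `zeroRate` fraction of cells is
#' then set to 0 and a `missingRate` fraction to `NA`, emulating the zero
#' and missing entries of real omics exports. All views share sample order
#' and labels. Generation is fully deterministic given the spec (including
#' its seed).
#'
#' @param spec a [CohortSpec-class] built with [cohortSpec()].
#' @return A list with elements `views` (list of [OmicsView-class], equal
#'   loss weights) and `labels` (integer vector of class labels `0..k-1`,
#'   named by sample id).
#' @examples
#' cohort <- generateCohort(cohortSpec(classSizes = c(10, 10), views = list(
#'   list(name = "v1", nFeatures = 20, nInformative = 4)), seed = 3))
#' table(cohort$labels)
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  n <- spec@nSamples
  k <- length(spec@classSizes)
  labels <- rep(seq_len(k) - 1L, spec@classSizes)
  ids <- sprintf("S%04d", seq_len(n))
  names(labels) <- ids
  m <- length(spec@views)

  views <- withr::with_seed(spec@seed, lapply(spec@views, function(v) {
    p <- v$nFeatures
    mat <- matrix(rnorm(n * p, mean = 0, sd = spec@noiseSd), n, p,
                  dimnames = list(ids, paste0(v$name, "_f", seq_len(p))))
    classes <- if (is.null(v$classes)) seq_len(k) - 1L else v$classes
    if (v$nInformative > 0 && length(classes) > 0) {
      # disjoint per-class blocks of informative features
      blocks <- split(seq_len(v$nInformative),
                      rep(seq_along(classes), length.out = v$nInformative))
      for (b in seq_along(classes)) {
        rows <- which(labels == classes[b])
        mat[rows, blocks[[b]]] <- mat[rows, blocks[[b]]] +
          spec@effectSize * spec@noiseSd
      }
    }
    if (spec@zeroRate > 0) {
      nz <- round(spec@zeroRate * length(mat))
      mat[sample(length(mat), nz)] <- 0
    }
    if (spec@missingRate > 0) {
      nm <- round(spec@missingRate * length(mat))
      mat[sample(length(mat), nm)] <- NA_real_
    }
    omicsView(v$name, mat, lossWeight = 1 / m)
  }))
  names(views) <- vapply(spec@views, `[[`, character(1), "name")
  list(views = views, labels = labels)
}

#' Write a cohort to tab-separated files
#'
#' Writes each view as a TSV with the sample id in the first column
#' (`sample_id`) and a header row of feature names, missing values coded
#' `NA`; labels go to `labels.tsv` with columns `sample_id` and `subtype`.
#'
#' @param cohort list as returned by [generateCohort()].
#' @param outdir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeCohort <- function(cohort, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (v in cohort$views) {
    f <- file.path(outdir, paste0(viewName(v), ".tsv"))
    writeMatrixTSV(viewMatrix(v), f)
    files <- c(files, f)
  }
  f <- file.path(outdir, "labels.tsv")
  data.table::fwrite(
    data.table::data.table(sample_id = names(cohort$labels),
                           subtype = unname(cohort$labels)),
    f, sep = "\t")
  invisible(c(files, f))
}

#' Read a labels file written by [writeCohort()]
#'
#' @param path two-column TSV (`sample_id`, `subtype`).
#' @return Integer labels named by sample id.
#' @export
readLabelsTSV <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (ncol(dt) != 2L)
    stop("labels file must have exactly two columns (sample_id, subtype): ", path)
  labels <- as.integer(dt[[2L]])
  names(labels) <- as.character(dt[[1L]])
  labels
}
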