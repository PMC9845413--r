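#' Read a matrix from the package's TSV dialect
#'
#' One header row of feature names, first column `sample_id`, tab separated,
#' `NA` for missing cells. This is the single matrix dialect used by every
#' stage of the pipeline.
#'
#' @param path file path.
#' @return Numeric matrix with sample ids as row names.
#' @export
readMatrixTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  if (ncol(dt) < 2L) stop("malformed TSV (need id column + data): ", path)
  ids <- as.character(dt[[1L]])
  bad <- names(dt)[-1L][!vapply(dt[, -1L], is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric column(s) in ", path, ": ", paste(bad, collapse = ", "))
  m <- as.matrix(dt[, -1L])
  rownames(m) <- ids
  m
}

#' Write a matrix in the package's TSV dialect
#'
#' @param m numeric matrix with sample ids as row names.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeMatrixTSV <- function(m, path) {
  # %.17g guarantees binary-lossless round trips through the text format
  chr <- ifelse(is.na(m), NA_character_, sprintf("%.17g", m))
  dt <- data.table::data.table(sample_id = rownames(m))
  dt <- cbind(dt, data.table::as.data.table(chr))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

pipelineDefaults <- function() {
  list(
    views = list(),            # named list: view name -> TSV path
    labels = NULL,             # labels TSV path
    outdir = ".",
    logViews = character(0),   # views to log2(v + 0.1)-transform (raw FPKM)
    ae = list(hiddenDims = c(500L, 200L, 500L), epochs = 100L,
              batchSize = 32L, learningRate = 0.001, viewWeights = NULL),
    snf = list(mu = 0.5, K = 20L, iterations = 20L, threshold = 0.8,
               graphInput = "fused"),   # or "latent"
    gcn = list(layerDims = c(64L, 32L, 16L), learningRate = 1e-4,
               weightDecay = 0.01, epochs = 1200L),
    cv = list(folds = 5L, repeats = 10L),
    seed = 1L
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML file and merges it over the package defaults. Recognized
#' top-level keys: `views` (named view -> path map), `labels`, `outdir`,
#' `logViews`, `ae`, `snf`, `gcn`, `cv`, `seed`.
#'
#' @param path YAML file.
#' @return A validated configuration list of class `pipelineConfig`.
#' @export
loadPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  pipelineConfig(user)
}

#' Assemble a pipeline configuration from a list
#'
#' @param config list of overrides over the defaults (see
#'   [loadPipelineConfig()] for the keys).
#' @return A validated configuration list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(config = list()) {
  cfg <- utils::modifyList(pipelineDefaults(), config)
  if (length(cfg$views) == 0L) stop("config: 'views' must map view names to files")
  if (is.null(names(cfg$views)) || any(!nzchar(names(cfg$views))))
    stop("config: 'views' must be a named map (view name -> path)")
  if (is.null(cfg$labels)) stop("config: 'labels' path is required")
  for (p in c(unlist(cfg$views), cfg$labels))
    if (!file.exists(p)) stop("config: referenced file does not exist: ", p)
  if (cfg$snf$threshold < -1 || cfg$snf$threshold > 1)
    stop("config: 'snf$threshold' must lie in [-1, 1]")
  structure(cfg, class = "pipelineConfig")
}

#' Run the full classification pipeline
#'
#' Stages, in order: read and align the views and labels; clean every view
#' ([preprocessView()]); train the weighted autoencoder and extract latent
#' features; build per-view similarity kernels and the fused network; build
#' the Pearson-thresholded patient graph; evaluate the residual GCN by
#' repeated stratified cross-validation. Every intermediate is persisted to
#' `outdir` (`<view>_clean.tsv`, `latent.tsv`, `ae_loss.tsv`, `fused.tsv`,
#' `adjacency.tsv`, `metrics.json`, `per_fold.tsv`, `pipeline.log`), and
#' the run is bit-reproducible given the master seed, which fans out to the
#' stage seeds by fixed offsets.
#'
#' @param config a `pipelineConfig` (see [pipelineConfig()] /
#'   [loadPipelineConfig()]).
#' @return The cross-validation [MetricsReport-class].
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file.path(config$outdir, "pipeline.log")
  logLines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    message(line)
    logLines <<- c(logLines, line)
  }
  seed <- as.integer(config$seed)
  aeSeed <- seed + 101L
  cvSeed <- seed + 202L
  say("stage=config seed=%d ae_seed=%d cv_seed=%d", seed, aeSeed, cvSeed)

  labels <- readLabelsTSV(config$labels)
  views <- lapply(names(config$views), function(nm) {
    omicsView(nm, readMatrixTSV(config$views[[nm]]))
  })
  names(views) <- names(config$views)
  ids <- names(labels)
  for (v in views) {
    if (!setequal(sampleIds(v), ids) || length(sampleIds(v)) != length(ids)) {
      off <- c(setdiff(sampleIds(v), ids), setdiff(ids, sampleIds(v)))
      stop("sample ids of view '", viewName(v), "' do not match the labels: ",
           paste(head(off, 10), collapse = ", "))
    }
  }
  views <- lapply(views, function(v)
    omicsView(viewName(v), viewMatrix(v)[ids, , drop = FALSE],
              lossWeight = lossWeight(v)))

  say("stage=preprocess views=%s log_views=%s",
      paste(names(views), collapse = ","),
      paste(config$logViews, collapse = ",") )
  clean <- lapply(views, function(v)
    preprocessView(v, logTransform = viewName(v) %in% config$logViews))
  for (v in clean)
    writeMatrixTSV(viewMatrix(v),
                   file.path(config$outdir, paste0(viewName(v), "_clean.tsv")))

  aeCfg <- aeConfig(hiddenDims = config$ae$hiddenDims,
                    epochs = config$ae$epochs,
                    batchSize = config$ae$batchSize,
                    learningRate = config$ae$learningRate,
                    viewWeights = config$ae$viewWeights,
                    seed = aeSeed)
  say("stage=train-ae hidden=%s epochs=%d batch=%d lr=%g",
      paste(aeCfg$hiddenDims, collapse = ","), aeCfg$epochs,
      aeCfg$batchSize, aeCfg$learningRate)
  ae <- trainAutoencoder(clean, aeCfg)
  writeMatrixTSV(latentMatrix(ae$latent), file.path(config$outdir, "latent.tsv"))
  data.table::fwrite(
    data.table::data.table(epoch = seq_along(ae$lossTrace), loss = ae$lossTrace),
    file.path(config$outdir, "ae_loss.tsv"), sep = "\t")

  say("stage=build-graph mu=%g K=%d iterations=%d threshold=%g input=%s",
      config$snf$mu, config$snf$K, config$snf$iterations,
      config$snf$threshold, config$snf$graphInput)
  bundle <- buildSimilarityBundle(lapply(clean, viewMatrix),
                                  mu = config$snf$mu, K = config$snf$K,
                                  iterations = config$snf$iterations)
  writeMatrixTSV(fusedMatrix(bundle), file.path(config$outdir, "fused.tsv"))
  graph <- if (identical(config$snf$graphInput, "latent"))
    buildPatientGraph(ae$latent, threshold = config$snf$threshold)
  else
    buildPatientGraph(bundle, threshold = config$snf$threshold)
  writeMatrixTSV(adjacency(graph), file.path(config$outdir, "adjacency.tsv"))
  say("stage=graph-built edges=%d", sum(adjacency(graph)) / 2)

  k <- length(unique(labels))
  gcnCfg <- rrgcnConfig(nClasses = k, layerDims = config$gcn$layerDims,
                        learningRate = config$gcn$learningRate,
                        weightDecay = config$gcn$weightDecay,
                        epochs = config$gcn$epochs)
  say("stage=evaluate folds=%d repeats=%d gcn_dims=%s lr=%g wd=%g epochs=%d",
      config$cv$folds, config$cv$repeats,
      paste(gcnCfg$layerDims, collapse = ","), gcnCfg$learningRate,
      gcnCfg$weightDecay, gcnCfg$epochs)
  report <- repeatedStratifiedCV(ae$latent, graph, unname(labels),
                                 cfg = gcnCfg, folds = config$cv$folds,
                                 repeats = config$cv$repeats, seed = cvSeed)

  data.table::fwrite(perFoldMetrics(report),
                     file.path(config$outdir, "per_fold.tsv"), sep = "\t")
  jsonlite::write_json(
    list(aggregate = as.list(aggregateMetrics(report)),
         per_class = perClassMetrics(report),
         n_repeats = report@nRepeats, n_folds = report@nFolds),
    file.path(config$outdir, "metrics.json"),
    auto_unbox = TRUE, digits = NA)
  say("stage=done accuracy=%.4f auc=%.4f",
      aggregateMetrics(report)[["accuracy"]], aggregateMetrics(report)[["auc"]])
  writeLines(logLines, logFile)
  report
}
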