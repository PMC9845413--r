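# macro precision/recall/F1 + accuracy from hard predictions
predMetrics <- function(yTrue, yPred) {
  classes <- sort(unique(yTrue))
  per <- vapply(classes, function(cl) {
    cc <- confusionCounts(yTrue, yPred, cl)
    prec <- if (cc["TP"] + cc["FP"] > 0) cc["TP"] / (cc["TP"] + cc["FP"]) else 0
    rec  <- if (cc["TP"] + cc["FN"] > 0) cc["TP"] / (cc["TP"] + cc["FN"]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(prec, rec, f1)
  }, numeric(3))
  c(accuracy = mean(yPred == yTrue),
    f1 = mean(per[3, ]), precision = mean(per[1, ]), recall = mean(per[2, ]))
}

#' Single- versus multi-omics ablation
#'
#' Runs the full pipeline (cleaning, weighted autoencoder, similarity
#' fusion, Pearson patient graph, cross-validated residual GCN) on each
#' single view and on all views together, reporting accuracy and macro AUC
#' per input set. This quantifies what each omics type contributes and
#' whether the fused views beat the best single view.
#'
#' @param views list of raw [OmicsView-class] objects (aligned samples).
#' @param labels integer labels `0..k-1` aligned with the views.
#' @param aeCfg autoencoder settings ([aeConfig()]); `viewWeights` is reset
#'   to 1 for single-view runs.
#' @param threshold Pearson edge threshold.
#' @param mu,K similarity-kernel parameters.
#' @param gcnCfg classifier settings ([rrgcnConfig()]).
#' @param folds,repeats,seed cross-validation protocol.
#' @param logViews names of views needing the log2(v + 0.1) transform.
#' @return data.frame with columns `input`, `accuracy`, `auc`: one row per
#'   single view plus one `multi-omics` row (omitted when only one view is
#'   given).
#' @export
runAblation <- function(views, labels, aeCfg = aeConfig(),
                        threshold = 0.8, mu = 0.5, K = 20L,
                        gcnCfg = rrgcnConfig(nClasses = length(unique(labels))),
                        folds = 5L, repeats = 1L, seed = 1L,
                        logViews = character(0)) {
  stopifnot(length(views) >= 1L)
  inputSets <- lapply(views, list)
  names(inputSets) <- vapply(views, viewName, character(1))
  if (length(views) > 1L) inputSets[["multi-omics"]] <- views

  rows <- lapply(names(inputSets), function(nm) {
    vs <- inputSets[[nm]]
    cfg <- aeCfg
    if (length(vs) == 1L) cfg$viewWeights <- 1
    clean <- lapply(vs, function(v)
      preprocessView(v, logTransform = viewName(v) %in% logViews))
    ae <- trainAutoencoder(clean, cfg)
    bundle <- buildSimilarityBundle(lapply(clean, viewMatrix), mu = mu, K = K)
    graph <- buildPatientGraph(bundle, threshold = threshold)
    rep <- repeatedStratifiedCV(ae$latent, graph, labels, cfg = gcnCfg,
                                folds = folds, repeats = repeats, seed = seed)
    agg <- aggregateMetrics(rep)
    data.frame(input = nm, accuracy = agg[["accuracy"]], auc = agg[["auc"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# CV accuracy of a fit/predict pair over precomputed folds
cvAccuracy <- function(X, y, foldId, fitPredict) {
  preds <- integer(length(y))
  for (f in sort(unique(foldId))) {
    test <- foldId == f
    preds[test] <- fitPredict(X[!test, , drop = FALSE], y[!test],
                              X[test, , drop = FALSE])
  }
  mean(preds == y)
}

# out-of-fold predictions with a fixed model
oofPredictions <- function(X, y, foldId, fitPredict) {
  preds <- integer(length(y))
  for (f in sort(unique(foldId))) {
    test <- foldId == f
    preds[test] <- fitPredict(X[!test, , drop = FALSE], y[!test],
                              X[test, , drop = FALSE])
  }
  preds
}

#' Classical baselines over the latent features
#'
#' Fits random-forest and support-vector baselines on the autoencoder's
#' latent feature matrix, tuning them by cross-validated grid search
#' (random forest: number of trees over 1..101 in steps of 10, then
#' `mtry` over 1..21; SVM: cost over {0.1, 1, 100, 1000}, gamma over
#' {1e-4, 1e-3, 5e-3, 0.1, 1, 3, 5}, linear and radial kernels), and
#' reports out-of-fold accuracy, macro F1, precision and recall per model
#' alongside the residual GCN evaluated with the same protocol. The
#' baselines are comparison fixtures built on established implementations.
#'
#' @param latent a [LatentFeatures-class].
#' @param labels integer labels `0..k-1`.
#' @param graph a [PatientGraph-class] for the RRGCN row.
#' @param gcnCfg an [rrgcnConfig()] for the RRGCN row.
#' @param folds cross-validation folds (default 5).
#' @param repeats repeats for the RRGCN row (default 1).
#' @param seed master seed; the whole table is deterministic given it.
#' @return data.frame with columns `model`, `accuracy`, `f1`, `precision`,
#'   `recall` and rows RF, SVM, RRGCN.
#' @export
runBaselines <- function(latent, labels, graph,
                         gcnCfg = rrgcnConfig(nClasses = length(unique(labels))),
                         folds = 5L, repeats = 1L, seed = 1L) {
  X <- latentMatrix(latent)
  y <- unname(labels)
  foldId <- stratifiedFolds(y, folds = folds, seed = seed)

  rfRow <- withr::with_seed(seed + 11L, {
    ntreeGrid <- seq(1L, 101L, by = 10L)
    mtryGrid <- seq_len(min(21L, ncol(X)))
    rfFit <- function(ntree, mtry) function(Xtr, ytr, Xte) {
      fit <- randomForest::randomForest(Xtr, factor(ytr, levels = sort(unique(y))),
                                        ntree = ntree, mtry = mtry)
      as.integer(as.character(predict(fit, Xte)))
    }
    defaultMtry <- max(1L, floor(sqrt(ncol(X))))
    accN <- vapply(ntreeGrid, function(nt)
      cvAccuracy(X, y, foldId, rfFit(nt, defaultMtry)), numeric(1))
    bestNtree <- ntreeGrid[which.max(accN)]
    accM <- vapply(mtryGrid, function(mt)
      cvAccuracy(X, y, foldId, rfFit(bestNtree, mt)), numeric(1))
    bestMtry <- mtryGrid[which.max(accM)]
    preds <- oofPredictions(X, y, foldId, rfFit(bestNtree, bestMtry))
    predMetrics(y, preds)
  })

  svmRow <- withr::with_seed(seed + 22L, {
    grid <- expand.grid(C = c(0.1, 1, 100, 1000),
                        gamma = c(1e-4, 1e-3, 5e-3, 0.1, 1, 3, 5),
                        kernel = c("linear", "radial"),
                        stringsAsFactors = FALSE)
    svmFit <- function(C, gamma, kernel) function(Xtr, ytr, Xte) {
      fit <- e1071::svm(Xtr, factor(ytr, levels = sort(unique(y))),
                        cost = C, gamma = gamma, kernel = kernel, scale = FALSE)
      as.integer(as.character(predict(fit, Xte)))
    }
    acc <- vapply(seq_len(nrow(grid)), function(i)
      cvAccuracy(X, y, foldId,
                 svmFit(grid$C[i], grid$gamma[i], grid$kernel[i])),
      numeric(1))
    best <- grid[which.max(acc), ]
    preds <- oofPredictions(X, y, foldId,
                            svmFit(best$C, best$gamma, best$kernel))
    predMetrics(y, preds)
  })

  gcnRep <- repeatedStratifiedCV(latent, graph, y, cfg = gcnCfg,
                                 folds = folds, repeats = repeats,
                                 seed = seed + 33L)
  agg <- aggregateMetrics(gcnRep)
  gcnRow <- c(accuracy = agg[["accuracy"]], f1 = agg[["f1"]],
              precision = agg[["precision"]], recall = agg[["recall"]])

  out <- rbind(data.frame(model = "RF", t(rfRow)),
               data.frame(model = "SVM", t(svmRow)),
               data.frame(model = "RRGCN", t(gcnRow)))
  rownames(out) <- NULL
  out
}
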