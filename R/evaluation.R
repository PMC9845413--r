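#' One-vs-rest confusion counts
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param positiveClass the class treated as positive.
#' @return Named integer vector `(TP, FP, FN, TN)`; the four counts sum to
#'   the number of samples.
#' @examples
#' confusionCounts(c(0, 0, 1, 1, 1), c(0, 1, 1, 1, 0), 1)  # TP 2 FP 1 FN 1 TN 1
#' @export
confusionCounts <- function(yTrue, yPred, positiveClass) {
  if (length(yTrue) != length(yPred))
    stop("'yTrue' and 'yPred' must have equal length")
  if (!positiveClass %in% c(yTrue, yPred))
    stop("unknown class label: ", positiveClass)
  tp <- sum(yTrue == positiveClass & yPred == positiveClass)
  fp <- sum(yTrue != positiveClass & yPred == positiveClass)
  fn <- sum(yTrue == positiveClass & yPred != positiveClass)
  tn <- sum(yTrue != positiveClass & yPred != positiveClass)
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

#' ROC AUC for one positive class
#'
#' Area under the curve of true positive rate `TP/(TP+FN)` against false
#' positive rate `FP/(FP+TN)` over all score thresholds, by trapezoidal
#' integration (ties contribute 1/2): equivalently the Mann-Whitney
#' concordance probability that a positive scores above a negative.
#'
#' @param yTrue label vector.
#' @param scores numeric scores, higher means more positive.
#' @param positiveClass class treated as positive.
#' @return AUC in \[0, 1\], or `NA` with a warning when `yTrue` has a single
#'   class.
#' @export
rocAUC <- function(yTrue, scores, positiveClass) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- yTrue == positiveClass
  if (all(pos) || !any(pos)) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  as.numeric(pROC::auc(pROC::roc(
    response = as.integer(pos), predictor = scores,
    levels = c(0, 1), direction = "<", quiet = TRUE)))
}

#' Precision-recall AUC (average precision) for one positive class
#'
#' The mean of the precision values attained at each recall threshold:
#' \eqn{\sum_i (R_i - R_{i-1}) P_i} over the distinct score thresholds in
#' decreasing order.
#'
#' @inheritParams rocAUC
#' @return Average precision in \[0, 1\], or `NA` with a warning when
#'   `yTrue` has a single class.
#' @export
prAUC <- function(yTrue, scores, positiveClass) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- as.integer(yTrue == positiveClass)
  nPos <- sum(pos)
  if (nPos == 0L || nPos == length(pos)) {
    warning("PR-AUC undefined: only one class present")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- pos[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  last <- c(s[-1] != s[-length(s)], TRUE)   # last index of each threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / nPos
  sum(diff(c(0, rec)) * prec)
}

#' Confusion-matrix metrics from class probabilities
#'
#' Predictions are the row-wise argmax of `yProb`. Precision `TP/(TP+FP)`,
#' recall (sensitivity) `TP/(TP+FN)`, their harmonic mean F1, ROC AUC and
#' PR-AUC are computed one-vs-rest per class and macro-averaged (unweighted
#' mean over the classes observed in `yTrue`); accuracy is the global
#' fraction of correctly predicted samples. Classes absent from `yTrue` are
#' excluded from the macro mean with a warning.
#'
#' @param yTrue integer labels `0..k-1`.
#' @param yProb n-by-k probability matrix, rows summing to 1; column j is
#'   the probability of class `j-1`.
#' @return List with `metrics` (named vector: precision, recall, f1,
#'   accuracy, auc, pr_auc) and `perClass` (one-vs-rest data.frame).
#' @export
classificationMetrics <- function(yTrue, yProb) {
  if (max(abs(rowSums(yProb) - 1)) > 1e-6)
    stop("rows of 'yProb' must sum to 1")
  k <- ncol(yProb)
  yPred <- max.col(yProb, ties.method = "first") - 1L
  classes <- seq_len(k) - 1L
  present <- classes %in% yTrue
  if (!all(present))
    warning("class(es) ", paste(classes[!present], collapse = ", "),
            " absent from yTrue; excluded from macro averages")
  perClass <- do.call(rbind, lapply(classes[present], function(cl) {
    cc <- confusionCounts(yTrue, yPred, cl)
    prec <- if (cc["TP"] + cc["FP"] > 0) cc["TP"] / (cc["TP"] + cc["FP"]) else 0
    rec  <- if (cc["TP"] + cc["FN"] > 0) cc["TP"] / (cc["TP"] + cc["FN"]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl,
               precision = unname(prec), recall = unname(rec), f1 = unname(f1),
               auc = rocAUC(yTrue, yProb[, cl + 1L], cl),
               pr_auc = prAUC(yTrue, yProb[, cl + 1L], cl))
  }))
  metrics <- c(precision = mean(perClass$precision),
               recall = mean(perClass$recall),
               f1 = mean(perClass$f1),
               accuracy = mean(yPred == yTrue),
               auc = mean(perClass$auc),
               pr_auc = mean(perClass$pr_auc))
  list(metrics = metrics, perClass = perClass)
}

#' Stratified fold assignment
#'
#' Assigns every sample to one of `folds` folds so that each class is spread
#' as evenly as possible across folds (within-class shuffling is seeded).
#'
#' @param labels class labels.
#' @param folds number of folds.
#' @param seed integer seed.
#' @return Integer fold id (1..folds) per sample.
#' @export
stratifiedFolds <- function(labels, folds = 5L, seed = 1L) {
  counts <- table(labels)
  if (any(counts < folds))
    stop("class(es) ", paste(names(counts)[counts < folds], collapse = ", "),
         " have fewer samples than folds (", folds, ")")
  assignment <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assignment
}

#' Repeated stratified cross-validation of the residual GCN
#'
#' The patient graph and latent features are built once on the full cohort
#' (transductive protocol); within each of `folds` stratified folds the
#' classifier is trained with the test nodes' labels masked out of the loss
#' and scored on the test nodes. The procedure is repeated `repeats` times
#' with fresh fold assignments (and fresh weight initializations), each
#' repeat's seed derived deterministically from the master seed, and the
#' per-fold metrics are averaged.
#'
#' @param latent a [LatentFeatures-class] for the full cohort.
#' @param graph a [PatientGraph-class] for the full cohort.
#' @param labels integer labels `0..k-1` aligned with the cohort.
#' @param cfg an [rrgcnConfig()] (its seed slot is overridden per fold).
#' @param folds folds per repeat (default 5).
#' @param repeats repetitions (default 10).
#' @param seed master seed.
#' @return A [MetricsReport-class].
#' @export
repeatedStratifiedCV <- function(latent, graph, labels,
                                 cfg = rrgcnConfig(nClasses = length(unique(labels))),
                                 folds = 5L, repeats = 10L, seed = 1L) {
  n <- length(labels)
  perFold <- list()
  perClass <- list()
  for (r in seq_len(repeats)) {
    foldId <- stratifiedFolds(labels, folds = folds, seed = seed + 1000L * r)
    for (f in seq_len(folds)) {
      testMask <- foldId == f
      foldCfg <- cfg
      foldCfg$seed <- as.integer(seed + 1000L * r + f)
      fit <- trainRRGCN(latent, graph, labels, trainMask = !testMask,
                        cfg = foldCfg)
      res <- classificationMetrics(labels[testMask],
                                   fit@probabilities[testMask, , drop = FALSE])
      perFold[[length(perFold) + 1L]] <-
        data.frame(repeat_ = r, fold = f, t(res$metrics))
      pc <- res$perClass
      pc$repeat_ <- r; pc$fold <- f
      perClass[[length(perClass) + 1L]] <- pc
    }
  }
  perFold <- do.call(rbind, perFold)
  perClassAll <- do.call(rbind, perClass)
  perClassAgg <- stats::aggregate(
    perClassAll[c("precision", "recall", "f1", "auc", "pr_auc")],
    by = list(class = perClassAll$class), FUN = mean)
  metricCols <- c("precision", "recall", "f1", "accuracy", "auc", "pr_auc")
  aggregate <- colMeans(perFold[metricCols], na.rm = TRUE)
  new("MetricsReport", perFold = perFold, aggregate = aggregate,
      perClass = perClassAgg, nRepeats = as.integer(repeats),
      nFolds = as.integer(folds))
}
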