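test_that("one-vs-rest confusion counts enumerate correctly", {
  expect_equal(confusionCounts(rep(c(1, 0), c(4, 6)), rep(c(1, 0), c(4, 6)), 1),
               c(TP = 4L, FP = 0L, FN = 0L, TN = 6L))
  expect_equal(confusionCounts(rep(c(1, 0), c(4, 6)), rep(1, 10), 1),
               c(TP = 4L, FP = 6L, FN = 0L, TN = 0L))
  cc <- confusionCounts(c(0, 0, 1, 1, 1), c(0, 1, 1, 1, 0), 1)
  expect_equal(cc, c(TP = 2L, FP = 1L, FN = 1L, TN = 1L))
  expect_equal(sum(cc), 5L)
  expect_error(confusionCounts(c(0, 1), c(0, 1), 7), "unknown class")
})

test_that("metrics on the hand confusion matrix (2,1,1,1) are 2/3, 2/3, 2/3, 3/5", {
  yTrue <- c(0, 0, 1, 1, 1)
  # probabilities whose argmax is (0, 1, 1, 1, 0)
  yProb <- rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.3, 0.7),
                 c(0.4, 0.6), c(0.8, 0.2))
  res <- classificationMetrics(yTrue, yProb)
  cls1 <- res$perClass[res$perClass$class == 1, ]
  expect_equal(cls1$precision, 2 / 3)
  expect_equal(cls1$recall, 2 / 3)
  expect_equal(cls1$f1, 2 / 3)
  expect_equal(unname(res$metrics["accuracy"]), 3 / 5)
})

test_that("perfect predictions score 1 everywhere; degenerate predictors at chance", {
  yTrue <- rep(0:3, times = c(3, 4, 5, 6))
  yProb <- matrix(1e-9, length(yTrue), 4)
  yProb[cbind(seq_along(yTrue), yTrue + 1L)] <- 1 - 3e-9
  res <- classificationMetrics(yTrue, yProb)
  expect_equal(unname(res$metrics[c("precision", "recall", "f1", "accuracy",
                                    "auc", "pr_auc")]),
               rep(1, 6))

  # constant single-class prediction on balanced binary data: accuracy 1/2
  yTrue2 <- rep(0:1, each = 5)
  yProb2 <- matrix(rep(c(0.7, 0.3), each = 10), 10, 2)
  res2 <- classificationMetrics(yTrue2, yProb2)
  expect_equal(unname(res2$metrics["accuracy"]), 0.5)
})

test_that("macro metrics are invariant under class relabeling", {
  withr::with_seed(14, {
    yTrue <- sample(0:2, 40, replace = TRUE)
    yProb <- matrix(runif(120), 40, 3)
    yProb <- yProb / rowSums(yProb)
    base <- classificationMetrics(yTrue, yProb)$metrics
    perm <- c(2L, 0L, 1L)   # relabel c -> perm[c+1]
    yTrueP <- perm[yTrue + 1L]
    yProbP <- yProb[, order(perm)]
    relab <- classificationMetrics(yTrueP, yProbP)$metrics
    expect_equal(relab, base, tolerance = 1e-12)
  })
})

test_that("F1 lies between precision and recall", {
  withr::with_seed(3, {
    for (i in 1:10) {
      yTrue <- sample(0:1, 30, replace = TRUE)
      yProb <- matrix(runif(60), 30, 2)
      yProb <- yProb / rowSums(yProb)
      pc <- classificationMetrics(yTrue, yProb)$perClass
      expect_true(all(pc$f1 >= pmin(pc$precision, pc$recall) - 1e-12))
      expect_true(all(pc$f1 <= pmax(pc$precision, pc$recall) + 1e-12))
    }
  })
})

test_that("ROC AUC equals the concordant-pair probability", {
  expect_equal(rocAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1), 1), 1)
  expect_equal(rocAUC(c(1, 0, 1, 0), rep(0.5, 4), 1), 0.5)
  expect_equal(rocAUC(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2), 1), 0.75)

  withr::with_seed(8, {
    for (i in 1:10) {
      n <- sample(6:30, 1)
      yTrue <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(rnorm(n), 1)   # rounding forces ties
      expect_equal(rocAUC(yTrue, scores, 1), oracleAUC(yTrue == 1, scores))
    }
  })
  expect_warning(a <- rocAUC(c(1, 1), c(0.2, 0.3), 1), "one class")
  expect_true(is.na(a))
})

test_that("average precision behaves at the extremes and on a hand case", {
  expect_equal(prAUC(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1), 1), 1)
  # ranking 1,0,1,0 by score: cumulative (tp, fp) = (1,0),(1,1),(2,1),(2,2);
  # recall steps 1/2 at precision 1 and 1/2 at precision 2/3
  expect_equal(prAUC(c(1, 0, 1, 0), c(0.9, 0.8, 0.4, 0.2), 1),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_warning(a <- prAUC(c(0, 0), c(0.2, 0.3), 1), "one class")
  expect_true(is.na(a))
})

test_that("stratified folds partition the cohort evenly within classes", {
  labels <- rep(0:3, times = c(25, 60, 51, 136))
  f <- stratifiedFolds(labels, folds = 5, seed = 2)
  expect_equal(length(f), 272L)
  expect_true(all(f %in% 1:5))
  # every sample in exactly one fold, per-class spread within 1
  for (cl in 0:3) {
    tab <- table(f[labels == cl])
    expect_lte(max(tab) - min(tab), 1)
  }
  expect_identical(f, stratifiedFolds(labels, folds = 5, seed = 2))
  expect_error(stratifiedFolds(c(0, 0, 0, 1), folds = 3), "fewer samples")
})

test_that("repeated stratified CV partitions, aggregates and reproduces", {
  tg <- local({
    n <- 30
    labels <- rep(0:1, each = 15)
    X <- toyMatrix(n, 6, seed = 2)
    X[labels == 1, 1:3] <- X[labels == 1, 1:3] + 4
    A <- randomAdjacency(n, seed = 3)
    g <- methods::new("PatientGraph", adjacency = A,
                      normalized = normalizeAdjacency(A))
    list(X = X, g = g, labels = labels)
  })
  cfg <- rrgcnConfig(nClasses = 2, layerDims = c(8L, 6L, 4L), epochs = 100L)
  rep1 <- repeatedStratifiedCV(tg$X, tg$g, tg$labels, cfg = cfg,
                               folds = 3, repeats = 2, seed = 5)
  pf <- perFoldMetrics(rep1)
  expect_equal(nrow(pf), 6L)
  expect_equal(aggregateMetrics(rep1)[["accuracy"]], mean(pf$accuracy))
  expect_true(all(aggregateMetrics(rep1) >= 0 & aggregateMetrics(rep1) <= 1))

  rep2 <- repeatedStratifiedCV(tg$X, tg$g, tg$labels, cfg = cfg,
                               folds = 3, repeats = 2, seed = 5)
  expect_identical(perFoldMetrics(rep1), perFoldMetrics(rep2))
  expect_identical(aggregateMetrics(rep1), aggregateMetrics(rep2))
})
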