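test_that("renormalized adjacency matches the brute-force dense formula", {
  # isolated nodes: identity
  expect_equal(normalizeAdjacency(matrix(0, 4, 4)), diag(4))
  # single edge, n = 2: all entries 1/2
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(normalizeAdjacency(A2), matrix(0.5, 2, 2))

  for (n in c(3, 5, 8, 12)) {
    for (s in 1:3) {
      A <- randomAdjacency(n, seed = n * 10 + s)
      Ahat <- normalizeAdjacency(A)
      expect_equal(Ahat, oracleNormAdj(A), tolerance = 1e-12)
      expect_equal(Ahat, t(Ahat), tolerance = 1e-12)
      expect_true(all(Ahat >= 0 & Ahat <= 1))
      # spectral bound of the renormalized operator
      expect_lte(max(eigen(Ahat, symmetric = TRUE,
                           only.values = TRUE)$values), 1 + 1e-9)
    }
  }
  expect_error(normalizeAdjacency(matrix(c(0, 1, 0, 0), 2, 2)), "symmetric")
})

test_that("a graph convolution layer is activation(Ahat H W)", {
  H <- matrix(1:6, 3, 2) * 1.0
  expect_equal(gcnLayer(H, diag(3), diag(2), "identity"), H)

  # 3-node path graph against an independent dense triple product
  A <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  Ahat <- normalizeAdjacency(A)
  W <- matrix(c(0.5, -1, 2, 0.3, 1, -0.2), 2, 3)
  want <- Ahat %*% H %*% W
  expect_equal(gcnLayer(H, Ahat, W, "identity"), want)
  expect_equal(gcnLayer(H, Ahat, W, "elu"),
               ifelse(want > 0, want, exp(want) - 1))

  # ELU(0) = 0: zero features stay zero
  expect_equal(gcnLayer(matrix(0, 3, 2), Ahat, W), matrix(0, 3, 3))
  expect_error(gcnLayer(H, Ahat, matrix(0, 3, 3)), "conform")
})

test_that("the residual block is elu(H + linear(X))", {
  X <- matrix(c(1, -2, 0.5, 3), 2, 2)
  H <- matrix(c(0.2, -0.4, 1, -2), 2, 2)
  B <- matrix(c(0.1, 0.2, -0.3, 0.5), 2, 2)
  b <- c(0.05, -0.1)
  want <- H + X %*% B + rep(1, 2) %o% b
  want <- ifelse(want > 0, want, exp(want) - 1)
  expect_equal(residualBlock(X, H, list(B = B, b = b)), want)
  # zero projection reduces to elu(H)
  expect_equal(residualBlock(X, H, list(B = matrix(0, 2, 2))),
               ifelse(H > 0, H, exp(H) - 1))
  # cancellation gives exactly zero (ELU(0) = 0)
  expect_equal(residualBlock(X, -X %*% B, list(B = B)), matrix(0, 2, 2))
  expect_error(residualBlock(X, H, list(B = matrix(0, 3, 2))), "does not map")
})

toyGraphFit <- function(n = 20, d = 6, k = 2, epochs = 5L, seed = 1) {
  X <- toyMatrix(n, d, seed = seed)
  A <- randomAdjacency(n, seed = seed + 1)
  g <- methods::new("PatientGraph", adjacency = A,
                    normalized = normalizeAdjacency(A))
  labels <- rep(seq_len(k) - 1L, length.out = n)
  cfg <- rrgcnConfig(nClasses = k, layerDims = c(8L, 6L, 4L),
                     epochs = epochs, seed = seed)
  list(X = X, g = g, labels = labels, cfg = cfg)
}

test_that("forward pass yields softmax rows and is permutation equivariant", {
  tg <- toyGraphFit(n = 15, k = 3)
  fit <- trainRRGCN(tg$X, tg$g, tg$labels, cfg = tg$cfg)
  probs <- rrgcnForward(tg$X, tg$g, fit@params)
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  expect_true(all(probs > 0 & probs < 1))

  perm <- withr::with_seed(4, sample(15))
  Ap <- adjacency(tg$g)[perm, perm]
  gp <- methods::new("PatientGraph", adjacency = Ap,
                     normalized = normalizeAdjacency(Ap))
  probsP <- rrgcnForward(tg$X[perm, ], gp, fit@params)
  expect_equal(probsP, probs[perm, ], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("without edges, duplicate feature rows get duplicate predictions", {
  tg <- toyGraphFit(n = 10, k = 2)
  X <- tg$X
  X[2, ] <- X[1, ]
  A0 <- matrix(0, 10, 10)
  g0 <- methods::new("PatientGraph", adjacency = A0,
                     normalized = normalizeAdjacency(A0))
  fit <- trainRRGCN(X, g0, tg$labels, cfg = tg$cfg)
  probs <- rrgcnForward(X, g0, fit@params)
  expect_equal(probs[1, ], probs[2, ], ignore_attr = TRUE)
})

test_that("masked cross-entropy matches closed forms", {
  # probability 1 on the true class: zero loss
  p <- diag(3)[c(1, 2, 3), ]
  expect_equal(classificationLoss(p, c(0, 1, 2)), 0)
  # uniform 4-class probabilities: log(4)
  expect_equal(classificationLoss(matrix(0.25, 2, 4), c(0, 3)), log(4),
               tolerance = 1e-9)
  # hand arithmetic on two nodes
  p2 <- rbind(c(0.5, 0.5), c(0.75, 0.25))
  expect_equal(classificationLoss(p2, c(0, 1)),
               -(log(0.5) + log(0.25)) / 2)
  # masking selects nodes
  expect_equal(classificationLoss(p2, c(0, 1), mask = c(TRUE, FALSE)),
               -log(0.5))
  expect_error(classificationLoss(p2, c(0, 1), mask = logical(2)), "empty")
  expect_error(classificationLoss(p2, c(0, 3)), "labels must lie")
})

test_that("training is deterministic and can overfit a separable two-block graph", {
  n <- 40
  labels <- rep(0:1, each = n / 2)
  X <- toyMatrix(n, 8, seed = 6)
  X[labels == 1, 1:4] <- X[labels == 1, 1:4] + 3
  A <- matrix(0, n, n)   # two within-class cliques
  A[1:20, 1:20] <- 1; A[21:40, 21:40] <- 1
  diag(A) <- 0
  g <- methods::new("PatientGraph", adjacency = A,
                    normalized = normalizeAdjacency(A))
  cfg <- rrgcnConfig(nClasses = 2, seed = 3)   # defaults: 1200 epochs
  fit <- trainRRGCN(X, g, labels, cfg = cfg)
  expect_lt(tail(fit@lossTrace, 1), log(2) / 10)

  fit2 <- trainRRGCN(X, g, labels, cfg = cfg)
  expect_identical(fit@probabilities, fit2@probabilities)
  expect_identical(fit@lossTrace, fit2@lossTrace)
})
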