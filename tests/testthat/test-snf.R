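test_that("scaled exponential kernel matches an independent elementwise oracle", {
  X <- matrix(c(0, 1, 2, 10), 4, 1)
  W <- scaledExponentialKernel(X, mu = 0.5, K = 2)
  expect_equal(W, oracleKernel(X, mu = 0.5, K = 2), tolerance = 1e-12,
               ignore_attr = TRUE)

  withr::with_seed(31, {
    for (i in 1:3) {
      Xr <- matrix(rnorm(8 * 3), 8, 3)
      Wr <- scaledExponentialKernel(Xr, mu = 0.5, K = 3)
      expect_equal(Wr, oracleKernel(Xr, mu = 0.5, K = 3), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_lt(max(abs(Wr - t(Wr))), 1e-12)
    }
  })
})

test_that("kernel of identical points is all ones; bad sizes are rejected", {
  X <- matrix(1, 5, 3)
  expect_equal(scaledExponentialKernel(X, K = 2), matrix(1, 5, 5),
               ignore_attr = TRUE)
  expect_error(scaledExponentialKernel(matrix(0, 2, 2), K = 1), "at least 3")
  expect_error(scaledExponentialKernel(matrix(0, 5, 2), K = 5), "smaller than")
  expect_warning(scaledExponentialKernel(toyMatrix(5, 2), mu = 0.9, K = 2),
                 "customary range")
})

test_that("full normalization has diagonal 1/2 and unit row sums", {
  for (s in 1:4) {
    W <- toyKernel(7, seed = s)
    P <- normalizeSimilarity(W)
    expect_equal(unname(diag(P)), rep(0.5, 7))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_equal(P, oracleNormalize(W), tolerance = 1e-12, ignore_attr = TRUE)
  }
  # uniform off-diagonal, n = 5: off-diagonal entries all 1/8
  W <- matrix(1, 5, 5)
  P <- normalizeSimilarity(W)
  expect_equal(unname(P[1, 2]), 1 / 8)
  # an isolated sample is an error
  W0 <- toyKernel(4)
  W0[2, -2] <- 0; W0[-2, 2] <- 0
  expect_error(normalizeSimilarity(W0), "isolated")
})

test_that("kNN affinity is row-stochastic over at most K supports", {
  W <- toyKernel(9, seed = 2)
  S <- knnAffinity(W, K = 3)
  expect_true(all(rowSums(S != 0) <= 3))
  expect_lt(max(abs(rowSums(S) - 1)), 1e-10)
  expect_true(all(S >= 0))

  # K = n - 1: row-normalized off-diagonal of W
  Sfull <- knnAffinity(W, K = 8)
  W0 <- W; diag(W0) <- 0
  expect_equal(Sfull, W0 / rowSums(W0), tolerance = 1e-12)

  # diagonal-dominant toy with K = 1: single entry 1 per row
  Wd <- matrix(0.01, 4, 4); diag(Wd) <- 1
  Wd[1, 2] <- Wd[2, 1] <- 0.9
  Wd[3, 4] <- Wd[4, 3] <- 0.8
  S1 <- knnAffinity(Wd, K = 1)
  expect_true(all(rowSums(S1 != 0) == 1))
  expect_equal(unname(rowSums(S1)), rep(1, 4))
})

test_that("one fusion round matches a hand-composed dense oracle", {
  withr::with_seed(12, {
    W1 <- toyKernel(4, seed = 1); W2 <- toyKernel(4, seed = 2)
    P1 <- normalizeSimilarity(W1); P2 <- normalizeSimilarity(W2)
    S1 <- knnAffinity(W1, K = 2); S2 <- knnAffinity(W2, K = 2)
    got <- snfFuse(list(P1, P2), list(S1, S2), iterations = 1L)

    renorm <- function(Q) {
      Q <- oracleNormalize(Q)
      (Q + t(Q)) / 2
    }
    Q1 <- renorm(S1 %*% P2 %*% t(S1))
    Q2 <- renorm(S2 %*% P1 %*% t(S2))
    expect_lt(max(abs(got$P[[1]] - Q1)), 1e-10)
    expect_lt(max(abs(got$P[[2]] - Q2)), 1e-10)

    # fused: symmetrized average balanced to unit row sums (independent loop)
    want <- (Q1 + Q2 + t(Q1) + t(Q2)) / 4
    while (max(abs(rowSums(want) - 1)) >= 1e-9) {
      d <- 1 / sqrt(rowSums(want))
      want <- diag(d) %*% want %*% diag(d)
    }
    expect_lt(max(abs(got$fused - want)), 1e-8)
    expect_equal(got$iterations, 1L)
  })
})

test_that("fusion preserves symmetry, nonnegativity and row sums; views stay equal when identical", {
  W <- toyKernel(6, seed = 4)
  P <- normalizeSimilarity(W); S <- knnAffinity(W, K = 3)
  out <- snfFuse(list(P, P), list(S, S), iterations = 50L)
  expect_identical(out$P[[1]], out$P[[2]])
  expect_identical(out$fused, t(out$fused))
  expect_true(all(out$fused >= 0))
  expect_lt(max(abs(rowSums(out$fused) - 1)), 1e-6)
  expect_lte(out$iterations, 50L)

  expect_error(snfFuse(list(P), list(S)), "at least 2 views")
})

test_that("fusion on two views contracts after the first rounds", {
  withr::with_seed(77, {
    for (rep in 1:3) {
      X1 <- matrix(rnorm(10 * 4), 10, 4)
      X2 <- matrix(rnorm(10 * 4), 10, 4)
      W <- lapply(list(X1, X2), scaledExponentialKernel, mu = 0.5, K = 4)
      P <- lapply(W, normalizeSimilarity)
      S <- lapply(W, knnAffinity, K = 4)
      deltas <- numeric(0)
      Pcur <- P
      for (r in 1:8) {
        nxt <- snfFuse(Pcur, S, iterations = 1L)
        deltas <- c(deltas, max(abs(nxt$P[[1]] - Pcur[[1]])))
        Pcur <- nxt$P
      }
      expect_true(all(diff(deltas[3:8]) <= 1e-9))
    }
  })
})

test_that("Pearson thresholding builds the expected binary graph", {
  # duplicated rows correlate at 1: edge
  M <- rbind(a = c(1, 2, 3, 1), b = c(1, 2, 3, 1), c = c(-1, -2, -3, -1))
  A <- pearsonAdjacency(M, threshold = 0.8)
  expect_equal(unname(A["a", "b"]), 1)
  # a row and its negation correlate at -1: no edge
  expect_equal(unname(A["a", "c"]), 0)
  expect_identical(A, t(A))
  expect_equal(unname(diag(A)), rep(0, 3))

  # three samples with hand-computable correlations: exactly one edge > 0.8
  M2 <- rbind(s1 = c(1, 2, 3, 4),
              s2 = c(1.1, 2.0, 3.2, 3.9),   # ~0.998 with s1
              s3 = c(4, 1, 3, 2))
  expect_gt(cor(M2["s1", ], M2["s2", ]), 0.8)
  expect_lt(cor(M2["s1", ], M2["s3", ]), 0.8)
  expect_lt(cor(M2["s2", ], M2["s3", ]), 0.8)
  A2 <- pearsonAdjacency(M2, threshold = 0.8)
  expect_equal(sum(A2) / 2, 1)

  # constant rows: correlation treated as 0, with a warning
  M3 <- rbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 4, 6))
  expect_warning(A3 <- pearsonAdjacency(M3, threshold = 0.5), "constant")
  expect_equal(sum(A3[1, ]), 0)
  expect_equal(unname(A3["b", "c"]), 1)
})

test_that("Pearson adjacency is invariant to positive affine row rescaling", {
  withr::with_seed(9, {
    M <- matrix(rnorm(6 * 10), 6, 10)
    A <- pearsonAdjacency(M, threshold = 0.2)
    scale <- runif(6, 0.5, 3)
    shift <- rnorm(6)
    M2 <- M * scale + shift
    expect_identical(pearsonAdjacency(M2, threshold = 0.2), A)
  })
})

test_that("buildSimilarityBundle produces a valid bundle and single-view fallback", {
  mats <- list(toyMatrix(8, 5, seed = 1), toyMatrix(8, 5, seed = 2))
  b <- buildSimilarityBundle(mats, K = 3)
  expect_s4_class(b, "SimilarityBundle")
  expect_true(validObject(b))
  # single view: the (balanced) normalized similarity stands in for fusion
  b1 <- buildSimilarityBundle(mats[1], K = 3)
  expect_identical(fusedMatrix(b1), t(fusedMatrix(b1)))
  expect_lt(max(abs(rowSums(fusedMatrix(b1)) - 1)), 1e-6)
})
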