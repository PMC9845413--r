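# shared fixture builders; everything is generated in code, seeded

toyMatrix <- function(n, p, seed = 1, prefix = "S") {
  withr::with_seed(seed,
    matrix(rnorm(n * p), n, p,
           dimnames = list(sprintf("%s%03d", prefix, seq_len(n)),
                           paste0("f", seq_len(p)))))
}

toyView <- function(n = 6, p = 4, seed = 1, name = "v") {
  omicsView(name, toyMatrix(n, p, seed))
}

# small two-view cohort with strong class structure, for pipeline-level tests
smallCohortSpec <- function(effectSize = 4, seed = 5, missingRate = 0.01,
                            zeroRate = 0.02) {
  cohortSpec(classSizes = c(10L, 20L, 15L, 35L),
             views = list(
               list(name = "v1", nFeatures = 60L, nInformative = 16L),
               list(name = "v2", nFeatures = 40L, nInformative = 8L)),
             effectSize = effectSize, missingRate = missingRate,
             zeroRate = zeroRate, seed = seed)
}

# a symmetric nonnegative kernel-like matrix with unit diagonal
toyKernel <- function(n, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(runif(n * n, 0.05, 1), n, n)
    W <- (W + t(W)) / 2
    diag(W) <- 1
    W
  })
}

# independent dense oracle for the scaled exponential kernel (Eqs 5-6 style)
oracleKernel <- function(X, mu, K) {
  n <- nrow(X)
  D <- as.matrix(dist(X))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      Ni <- setdiff(order(D[i, ]), i)[seq_len(K)]
      Nj <- setdiff(order(D[j, ]), j)[seq_len(K)]
      epsij <- (mean(D[i, Ni]) + mean(D[j, Nj]) + D[i, j]) / 3
      W[i, j] <- if (D[i, j] == 0) 1 else exp(-D[i, j]^2 / (mu * epsij))
    }
  }
  (W + t(W)) / 2
}

# independent oracle for the full normalization (loop-based)
oracleNormalize <- function(W) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- sum(W[i, -i])
    for (j in seq_len(n)) P[i, j] <- if (i == j) 0.5 else W[i, j] / (2 * s)
  }
  P
}

# concordant-pair AUC oracle (ties count 1/2)
oracleAUC <- function(yPos, scores) {
  pos <- which(yPos); neg <- which(!yPos)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# brute-force renormalized adjacency via explicit degree matrix
oracleNormAdj <- function(A) {
  At <- A + diag(nrow(A))
  Dm <- diag(rowSums(At))
  Ds <- diag(1 / sqrt(diag(Dm)))
  Ds %*% At %*% Ds
}

randomAdjacency <- function(n, pEdge = 0.4, seed = 1) {
  withr::with_seed(seed, {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    A[up] <- rbinom(sum(up), 1, pEdge)
    A + t(A)
  })
}
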