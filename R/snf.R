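#' Scaled exponential similarity kernel
#'
#' Computes the patient-by-patient similarity kernel
#' \deqn{W(i,j) = \exp\left(-\frac{\rho^2(x_i, x_j)}{\mu\,\varepsilon(i,j)}\right)}
#' with \eqn{\rho} the Euclidean distance and the local scale
#' \eqn{\varepsilon(i,j) = [\mathrm{mean}\,\rho(x_i, N_i) +
#' \mathrm{mean}\,\rho(x_j, N_j) + \rho(x_i, x_j)]/3}, where \eqn{N_i} is the
#' set of the K nearest neighbours of sample i. The local scale removes the
#' dependence on the overall magnitude of the distances. W is symmetric with
#' unit diagonal; pairs at zero distance get similarity 1.
#'
#' @param X samples-by-features numeric matrix.
#' @param mu scaling factor; values in \[0.3, 0.8\] are customary (a warning
#'   is issued outside this range). Default 0.5.
#' @param K neighbourhood size, `K < n`. Default 20.
#' @return n-by-n symmetric kernel matrix with unit diagonal.
#' @examples
#' X <- matrix(c(0, 1, 2, 10), 4, 1)
#' scaledExponentialKernel(X, mu = 0.5, K = 2)
#' @export
scaledExponentialKernel <- function(X, mu = 0.5, K = 20L) {
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 samples (got ", n, ")")
  if (K >= n) stop("K (", K, ") must be smaller than the number of samples (", n, ")")
  if (mu < 0.3 || mu > 0.8)
    warning("mu = ", mu, " is outside the customary range [0.3, 0.8]")
  D <- as.matrix(stats::dist(X))
  # mean distance to the K nearest neighbours (self excluded)
  meanK <- vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i], method = "radix")[seq_len(K)]
    mean(d)
  }, numeric(1))
  eps <- (outer(meanK, meanK, "+") + D) / 3
  W <- exp(-(D^2) / (mu * eps))
  W[D == 0] <- 1   # identical points (and the diagonal): similarity 1
  dimnames(W) <- list(rownames(X), rownames(X))
  (W + t(W)) / 2
}

#' Full normalization of a similarity kernel
#'
#' \deqn{P(i,j) = \frac{W(i,j)}{2\sum_{k\ne i} W(i,k)} \;(j \ne i), \qquad
#' P(i,i) = 1/2.}
#' Each off-diagonal row sums to 1/2 and every row sums to 1, so P carries
#' half the probability mass on the sample itself; this makes the
#' cross-diffusion fusion numerically stable.
#'
#' @param W nonnegative square matrix with positive off-diagonal row sums.
#' @return Row-stochastic matrix with diagonal exactly 1/2.
#' @export
normalizeSimilarity <- function(W) {
  n <- nrow(W)
  W0 <- W
  diag(W0) <- 0
  off <- rowSums(W0)   # summed with the diagonal zeroed: no cancellation
                       # when off-diagonal entries are many orders below 1
  if (any(off <= 0))
    stop("isolated sample(s) with all-zero off-diagonal similarity: row ",
         paste(which(off <= 0), collapse = ", "))
  P <- W / (2 * off)
  diag(P) <- 0.5
  P
}

#' k-nearest-neighbour affinity matrix
#'
#' \deqn{S(i,j) = \frac{W(i,j)}{\sum_{k \in N_i} W(i,k)} \; (j \in N_i),
#' \qquad 0 \text{ otherwise},}
#' where \eqn{N_i} holds the K neighbours of i with the largest similarity
#' (self excluded, ties broken by first index). Each row is stochastic over
#' at most K supports: the affinity encodes only local structure.
#'
#' @param W nonnegative square similarity matrix.
#' @param K neighbourhood size, `K < n`.
#' @return Row-stochastic sparse-support matrix.
#' @export
knnAffinity <- function(W, K = 20L) {
  n <- nrow(W)
  if (K >= n) stop("K (", K, ") must be smaller than the number of samples (", n, ")")
  S <- matrix(0, n, n, dimnames = dimnames(W))
  for (i in seq_len(n)) {
    w <- W[i, ]
    w[i] <- -Inf
    nb <- order(w, decreasing = TRUE)[seq_len(K)]
    S[i, nb] <- W[i, nb] / sum(W[i, nb])
  }
  S
}

#' Fuse per-view similarity matrices by cross-diffusion
#'
#' Iterates the similarity network fusion update for each view v:
#' \deqn{P_v \leftarrow S_v \left(\frac{\sum_{k\ne v} P_k}{m-1}\right) S_v^T,}
#' i.e. each view's full similarity is diffused through its own local kNN
#' affinity while averaging the complementary views. After each round every
#' updated matrix is (optionally) renormalized with [normalizeSimilarity()]
#' and symmetrized, which keeps the iteration on the space of row-stochastic
#' symmetric-support matrices. Iteration stops early when the largest
#' elementwise change falls below `tol`. The fused network is the symmetrized
#' average of the m final matrices, balanced by symmetric diagonal scaling so
#' that it is exactly symmetric with unit row sums.
#'
#' @param P list of m full normalized similarity matrices (see
#'   [normalizeSimilarity()]); m >= 2.
#' @param S list of m kNN affinity matrices (see [knnAffinity()]).
#' @param iterations maximum fusion rounds (default 20).
#' @param tol early-stopping tolerance on the max-norm change (default 1e-6).
#' @param renormalize renormalize and symmetrize after every round (default
#'   `TRUE`).
#' @return List with `fused` (n-by-n symmetric matrix), `P` (final per-view
#'   matrices) and `iterations` (rounds performed).
#' @export
snfFuse <- function(P, S, iterations = 20L, tol = 1e-6, renormalize = TRUE) {
  m <- length(P)
  if (m < 2L)
    stop("similarity fusion needs at least 2 views; with a single view use ",
         "its normalized similarity matrix directly")
  if (length(S) != m) stop("'P' and 'S' must have the same length")
  it <- 0L
  for (r in seq_len(iterations)) {
    Pprev <- P
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      avg <- Reduce(`+`, Pprev[-v]) / (m - 1)
      Q <- S[[v]] %*% avg %*% t(S[[v]])
      if (renormalize) {
        Q <- normalizeSimilarity(Q)
        Q <- (Q + t(Q)) / 2
      }
      Pnew[[v]] <- Q
    }
    P <- Pnew
    it <- r
    delta <- max(vapply(seq_len(m),
                        function(v) max(abs(P[[v]] - Pprev[[v]])), numeric(1)))
    if (delta < tol) break
  }
  fused <- (Reduce(`+`, P) + Reduce(`+`, lapply(P, t))) / (2 * m)
  if (renormalize) fused <- symmetricBalance(fused)
  list(fused = fused, P = P, iterations = it)
}

# Symmetric diagonal balancing (Sinkhorn-type): rescales a positive symmetric
# matrix as D A D until every row sums to 1, preserving exact symmetry.
symmetricBalance <- function(A, tol = 1e-9, maxIter = 200L) {
  for (i in seq_len(maxIter)) {
    r <- rowSums(A)
    if (max(abs(r - 1)) < tol) break
    d <- 1 / sqrt(r)
    A <- A * outer(d, d)
  }
  A
}

#' Threshold patient correlations into a binary adjacency matrix
#'
#' Two patients are connected when the Pearson correlation of their profile
#' rows exceeds `threshold` (strictly). Constant rows have undefined
#' correlation; these are treated as correlation 0 with a warning.
#'
#' @param M n-by-p matrix of patient profiles (rows are patients); by
#'   convention the rows of the fused similarity network, or alternatively
#'   the latent feature matrix.
#' @param threshold correlation threshold in \[-1, 1\]; default 0.8, where
#'   classifier performance peaks in threshold sweeps.
#' @return n-by-n binary symmetric adjacency with zero diagonal.
#' @examples
#' M <- rbind(a = c(1, 2, 3), b = c(2, 4, 6.2), c = c(3, -1, 0))
#' pearsonAdjacency(M, threshold = 0.8)
#' @export
pearsonAdjacency <- function(M, threshold = 0.8) {
  if (threshold < -1 || threshold > 1) stop("'threshold' must lie in [-1, 1]")
  if (ncol(M) < 2L) stop("need at least 2 profile columns per patient")
  constant <- apply(M, 1L, function(x) sd(x) == 0)
  if (any(constant))
    warning(sum(constant), " constant patient profile(s); their correlations",
            " are treated as 0")
  C <- suppressWarnings(cor(t(M)))
  C[is.na(C)] <- 0
  A <- (C > threshold) * 1
  diag(A) <- 0
  A <- A * (t(A) == 1)   # guard symmetry against numeric asymmetry in cor()
  dimnames(A) <- list(rownames(M), rownames(M))
  A
}

#' Build per-view similarity matrices and the fused patient network
#'
#' Convenience wrapper running the full similarity stage: a scaled
#' exponential kernel per view, its full normalization and kNN affinity, and
#' the cross-diffusion fusion (for a single view the normalized similarity is
#' used directly as the fused network).
#'
#' @param matrices list of samples-by-features matrices, one per view (for
#'   example the cleaned per-view data), aligned on sample order.
#' @param mu kernel scaling factor (default 0.5).
#' @param K neighbourhood size (default 20).
#' @param iterations maximum fusion rounds (default 20).
#' @param renormalize see [snfFuse()].
#' @return A [SimilarityBundle-class].
#' @export
buildSimilarityBundle <- function(matrices, mu = 0.5, K = 20L,
                                  iterations = 20L, renormalize = TRUE) {
  W <- lapply(matrices, scaledExponentialKernel, mu = mu, K = K)
  P <- lapply(W, normalizeSimilarity)
  S <- lapply(W, knnAffinity, K = K)
  if (length(matrices) == 1L) {
    fused <- symmetricBalance((P[[1L]] + t(P[[1L]])) / 2)
    it <- 0L
  } else {
    fit <- snfFuse(P, S, iterations = iterations, renormalize = renormalize)
    fused <- fit$fused
    it <- fit$iterations
  }
  new("SimilarityBundle", W = W, P = P, S = S, fused = fused,
      params = list(mu = mu, K = as.integer(K), iterations = as.integer(it)))
}
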