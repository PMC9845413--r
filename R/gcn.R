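#' Exponential linear unit
#'
#' `elu(z) = z` for `z > 0` and `alpha * (exp(z) - 1)` otherwise.
#'
#' @param z numeric vector or matrix.
#' @param alpha saturation scale (default 1).
#' @return Same shape as `z`.
#' @export
elu <- function(z, alpha = 1) ifelse(z > 0, z, alpha * (exp(z) - 1))

# derivative of elu w.r.t. its pre-activation (alpha = 1)
eluGrad <- function(z) ifelse(z > 0, 1, exp(z))

#' Symmetric renormalized adjacency
#'
#' Computes the graph-convolution propagation matrix
#' \eqn{\hat A = \tilde D^{-1/2} \tilde A \tilde D^{-1/2}} with
#' \eqn{\tilde A = A + I} (self-loops added) and \eqn{\tilde D} its degree
#' matrix. The result is symmetric, entries lie in \[0, 1\], and its largest
#' eigenvalue is at most 1, which keeps repeated propagation stable.
#'
#' @param A binary symmetric adjacency with zero diagonal.
#' @return The n-by-n propagation matrix.
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2)
#' normalizeAdjacency(A)  # all entries 0.5
#' @export
normalizeAdjacency <- function(A) {
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  if (!isTRUE(all.equal(A, t(A), check.attributes = FALSE)))
    stop("adjacency must be symmetric")
  Atil <- A + diag(nrow(A))
  dInv <- 1 / sqrt(rowSums(Atil))
  Ahat <- Atil * outer(dInv, dInv)
  dimnames(Ahat) <- dimnames(A)
  Ahat
}

#' Build the patient graph from similarity profiles
#'
#' Thresholds the Pearson correlations of patient profiles into a binary
#' adjacency ([pearsonAdjacency()]) and attaches the renormalized
#' propagation matrix ([normalizeAdjacency()]). The default profile for a
#' patient is their row of the fused similarity network; the latent feature
#' matrix can be used instead.
#'
#' @param x a [SimilarityBundle-class] (rows of the fused network are the
#'   profiles), a [LatentFeatures-class], or a plain profile matrix with one
#'   row per patient.
#' @param threshold Pearson threshold (default 0.8).
#' @return A [PatientGraph-class].
#' @export
setGeneric("buildPatientGraph",
           function(x, threshold = 0.8) standardGeneric("buildPatientGraph"))

#' @rdname buildPatientGraph
#' @export
setMethod("buildPatientGraph", "matrix", function(x, threshold = 0.8) {
  A <- pearsonAdjacency(x, threshold)
  new("PatientGraph", adjacency = A, normalized = normalizeAdjacency(A))
})

#' @rdname buildPatientGraph
#' @export
setMethod("buildPatientGraph", "SimilarityBundle", function(x, threshold = 0.8) {
  # self-similarity carries no information about which OTHER patients a
  # profile resembles and its dominant diagonal entry (1/2 by construction)
  # would swamp the row correlations, so it is excluded from the profiles
  prof <- fusedMatrix(x)
  diag(prof) <- 0
  buildPatientGraph(prof, threshold)
})

#' @rdname buildPatientGraph
#' @export
setMethod("buildPatientGraph", "LatentFeatures", function(x, threshold = 0.8) {
  buildPatientGraph(latentMatrix(x), threshold)
})

#' One graph convolution layer
#'
#' `activation(A_hat %*% H %*% W)`: node features are averaged over the
#' (renormalized) neighbourhood, linearly transformed, and passed through
#' the nonlinearity.
#'
#' @param H n-by-d node feature matrix.
#' @param Ahat n-by-n propagation matrix (see [normalizeAdjacency()]).
#' @param W d-by-d' layer weight matrix.
#' @param activation `"elu"` or `"identity"`.
#' @return n-by-d' matrix.
#' @export
gcnLayer <- function(H, Ahat, W, activation = c("elu", "identity")) {
  activation <- match.arg(activation)
  if (ncol(Ahat) != nrow(H)) stop("Ahat and H do not conform")
  if (ncol(H) != nrow(W)) stop("H and W do not conform")
  Z <- Ahat %*% H %*% W
  if (activation == "elu") elu(Z) else Z
}

#' Residual (skip-connection) block output
#'
#' `elu(H + X %*% B + b)`: the block input X is sent through an independent
#' linear layer and added to the pre-activation block output, compensating
#' the information lost across the graph-convolution layers.
#'
#' @param X n-by-d node feature matrix (the block input).
#' @param H n-by-d' pre-activation output of the wrapped layers.
#' @param proj list with projection matrix `B` (d-by-d') and bias `b`
#'   (length d', default zeros).
#' @return n-by-d' matrix.
#' @export
residualBlock <- function(X, H, proj) {
  B <- proj$B
  b <- proj$b %||% numeric(ncol(H))
  if (ncol(X) != nrow(B) || ncol(B) != ncol(H))
    stop("projection does not map X (", ncol(X), " cols) to H (",
         ncol(H), " cols)")
  elu(sweep(H + X %*% B, 2L, b, "+"))
}

#' Residual GCN configuration
#'
#' Hyperparameters of the four-layer residual graph convolutional
#' classifier: graph-convolution widths 64, 32, 16 and the number of
#' classes; ELU activations; softmax output; Adam with learning rate 1e-4
#' and weight decay 0.01; 1200 training epochs.
#'
#' @param nClasses number of subtype classes (the width of the last layer).
#' @param layerDims widths of the first three graph-convolution layers.
#' @param learningRate Adam learning rate.
#' @param weightDecay L2 weight decay added to all parameter gradients.
#' @param epochs training epochs.
#' @param seed integer seed for weight initialization.
#' @return A validated list of class `rrgcnConfig` whose `layerDims` has the
#'   class count appended (four entries in total).
#' @export
rrgcnConfig <- function(nClasses, layerDims = c(64L, 32L, 16L),
                        learningRate = 1e-4, weightDecay = 0.01,
                        epochs = 1200L, seed = 1L) {
  layerDims <- as.integer(c(layerDims, nClasses))
  if (length(layerDims) != 4L || any(layerDims < 1L))
    stop("need three positive hidden widths plus a positive class count")
  structure(list(layerDims = layerDims, activation = "elu",
                 learningRate = learningRate, weightDecay = weightDecay,
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "rrgcnConfig")
}

# Glorot-initialized parameter list for input width d and the four layer
# widths of cfg; consumes the RNG stream.
initRRGCNParams <- function(d, layerDims) {
  list(W1 = glorot(d, layerDims[1]),
       W2 = glorot(layerDims[1], layerDims[2]),
       B1 = glorot(d, layerDims[2]), b1 = numeric(layerDims[2]),
       W3 = glorot(layerDims[2], layerDims[3]),
       W4 = glorot(layerDims[3], layerDims[4]),
       B2 = glorot(d, layerDims[4]), b2 = numeric(layerDims[4]))
}

rowSoftmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# Full forward pass; returns intermediates for backprop.
rrgcnForwardCache <- function(X, Ahat, par, AX = NULL) {
  if (is.null(AX)) AX <- Ahat %*% X
  Z1 <- AX %*% par$W1
  H1 <- elu(Z1)
  AH1 <- Ahat %*% H1
  Z2 <- AH1 %*% par$W2 + sweep(X %*% par$B1, 2L, par$b1, "+")
  H2 <- elu(Z2)
  AH2 <- Ahat %*% H2
  Z3 <- AH2 %*% par$W3
  H3 <- elu(Z3)
  AH3 <- Ahat %*% H3
  Z4 <- AH3 %*% par$W4 + sweep(X %*% par$B2, 2L, par$b2, "+")
  H4 <- elu(Z4)
  probs <- rowSoftmax(H4)
  list(AX = AX, Z1 = Z1, H1 = H1, AH1 = AH1, Z2 = Z2, H2 = H2, AH2 = AH2,
       Z3 = Z3, H3 = H3, AH3 = AH3, Z4 = Z4, H4 = H4, probs = probs)
}

#' Forward pass of the residual GCN
#'
#' Architecture: two residual blocks over four graph-convolution layers,
#' `[GCN(64) -> GCN(32) + skip1(X)] -> [GCN(16) -> GCN(k) + skip2(X)]`,
#' followed by a row softmax. Both skip connections project the original
#' node-feature matrix X through independent linear layers. ELU is the
#' nonlinearity throughout.
#'
#' @param latent a [LatentFeatures-class] or plain n-by-d matrix (node
#'   features X).
#' @param graph a [PatientGraph-class] over the same n samples.
#' @param params parameter list as stored in an [RRGCNFit-class] (slot
#'   `params`).
#' @return n-by-k matrix of class probabilities; every row sums to 1.
#' @export
rrgcnForward <- function(latent, graph, params) {
  X <- if (is(latent, "LatentFeatures")) latentMatrix(latent) else latent
  Ahat <- normalizedAdjacency(graph)
  if (nrow(X) != nrow(Ahat))
    stop("feature matrix has ", nrow(X), " rows but the graph has ",
         nrow(Ahat), " nodes")
  out <- rrgcnForwardCache(X, Ahat, params)$probs
  if (any(!is.finite(out)))
    stop("non-finite activations in the softmax layer")
  rownames(out) <- rownames(X)
  out
}

#' Masked cross-entropy classification loss
#'
#' Mean over the masked (training) nodes of the negative log probability
#' assigned to the true class; the multi-class generalization of the binary
#' cross-entropy, computed from the softmax output.
#'
#' @param probs n-by-k probability matrix (rows sum to 1).
#' @param labels integer class labels `0..k-1`, length n.
#' @param mask logical vector of length n, or integer node indices,
#'   selecting the nodes that contribute to the loss (default: all).
#' @return Nonnegative scalar.
#' @examples
#' p <- matrix(0.25, 2, 4)
#' classificationLoss(p, c(0, 3))  # log(4)
#' @export
classificationLoss <- function(probs, labels, mask = NULL) {
  n <- nrow(probs)
  if (length(labels) != n) stop("'labels' must have one entry per row of 'probs'")
  if (any(labels < 0 | labels >= ncol(probs)))
    stop("labels must lie in 0..", ncol(probs) - 1L)
  idx <- if (is.null(mask)) seq_len(n)
         else if (is.logical(mask)) which(mask) else as.integer(mask)
  if (length(idx) == 0L) stop("empty training mask")
  pTrue <- probs[cbind(idx, labels[idx] + 1L)]
  -mean(log(pTrue))
}

#' Train the residual GCN transductively
#'
#' All nodes and edges participate in message passing; only the nodes
#' selected by `trainMask` contribute to the masked cross-entropy loss, so
#' held-out patients are scored without their labels ever entering training.
#' Optimization is full-batch Adam with L2 weight decay for a fixed number
#' of epochs. Deterministic given `cfg$seed`.
#'
#' @param latent a [LatentFeatures-class] (or n-by-d matrix): node features.
#' @param graph a [PatientGraph-class].
#' @param labels integer class labels `0..k-1`, length n, aligned with the
#'   graph's sample order.
#' @param trainMask logical length-n vector (or node indices) marking
#'   training nodes; default all nodes.
#' @param cfg an [rrgcnConfig()]; its last layer width must equal the number
#'   of classes.
#' @return An [RRGCNFit-class] with trained parameters, the per-epoch masked
#'   loss trace, and softmax probabilities for every node.
#' @export
trainRRGCN <- function(latent, graph, labels, trainMask = NULL,
                       cfg = rrgcnConfig(nClasses = length(unique(labels)))) {
  stopifnot(inherits(cfg, "rrgcnConfig"))
  X <- if (is(latent, "LatentFeatures")) latentMatrix(latent) else latent
  Ahat <- normalizedAdjacency(graph)
  n <- nrow(X)
  if (nrow(Ahat) != n) stop("graph and feature matrix disagree on n")
  if (length(labels) != n) stop("need one label per node")
  k <- cfg$layerDims[4L]
  if (any(labels < 0 | labels >= k))
    stop("labels must lie in 0..", k - 1L, " (last layer width ", k, ")")
  mask <- if (is.null(trainMask)) rep(TRUE, n)
          else if (is.logical(trainMask)) trainMask
          else seq_len(n) %in% as.integer(trainMask)
  if (!any(mask)) stop("empty training mask")

  Y <- matrix(0, n, k)
  Y[cbind(seq_len(n), labels + 1L)] <- 1
  nMask <- sum(mask)

  withr::with_seed(cfg$seed, {
    par <- initRRGCNParams(ncol(X), cfg$layerDims)
    opt <- adamInit(par, lr = cfg$learningRate, weightDecay = cfg$weightDecay)
    AX <- Ahat %*% X
    lossTrace <- numeric(cfg$epochs)
    for (epoch in seq_len(cfg$epochs)) {
      fw <- rrgcnForwardCache(X, Ahat, par, AX = AX)
      loss <- classificationLoss(fw$probs, labels, mask)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch)
      lossTrace[epoch] <- loss

      # softmax + cross-entropy gradient, masked and averaged over train nodes
      G4 <- (fw$probs - Y) / nMask
      G4[!mask, ] <- 0
      dZ4 <- G4 * eluGrad(fw$Z4)
      dW4 <- crossprod(fw$AH3, dZ4)
      dB2 <- crossprod(X, dZ4)
      db2 <- colSums(dZ4)
      dH3 <- (Ahat %*% dZ4) %*% t(par$W4)     # Ahat symmetric
      dZ3 <- dH3 * eluGrad(fw$Z3)
      dW3 <- crossprod(fw$AH2, dZ3)
      dH2 <- (Ahat %*% dZ3) %*% t(par$W3)
      dZ2 <- dH2 * eluGrad(fw$Z2)
      dW2 <- crossprod(fw$AH1, dZ2)
      dB1 <- crossprod(X, dZ2)
      db1 <- colSums(dZ2)
      dH1 <- (Ahat %*% dZ2) %*% t(par$W2)
      dZ1 <- dH1 * eluGrad(fw$Z1)
      dW1 <- crossprod(AX, dZ1)

      grads <- list(W1 = dW1, W2 = dW2, B1 = dB1, b1 = db1,
                    W3 = dW3, W4 = dW4, B2 = dB2, b2 = db2)
      st <- adamStep(opt, par, grads)
      opt <- st$state; par <- st$params
    }
  })

  probs <- rrgcnForwardCache(X, Ahat, par)$probs
  rownames(probs) <- rownames(X)
  colnames(probs) <- paste0("class", seq_len(k) - 1L)
  new("RRGCNFit", params = par, lossTrace = as.numeric(lossTrace),
      probabilities = probs, config = unclass(cfg))
}
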