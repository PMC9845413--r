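#' Autoencoder configuration
#'
#' Hyperparameters of the dimension-reducing autoencoder: one fully connected
#' encoder/decoder stack over the concatenated views, three hidden layers of
#' sizes `hiddenDims` (the middle size is the latent dimension d), sigmoid
#' activations on every layer including the output, mean-squared-error
#' reconstruction loss weighted per view, trained with Adam.
#'
#' @param hiddenDims integer triple (encoder, latent, decoder widths).
#' @param epochs training epochs (fixed; no early stopping).
#' @param batchSize minibatch size.
#' @param learningRate Adam learning rate.
#' @param viewWeights per-view loss weights summing to 1, or `NULL` to use
#'   0.4/0.3/0.3 for three views (expression weighted highest) and equal
#'   weights otherwise.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return A validated list of class `aeConfig`.
#' @export
aeConfig <- function(hiddenDims = c(500L, 200L, 500L), epochs = 100L,
                     batchSize = 32L, learningRate = 0.001,
                     viewWeights = NULL, seed = 1L) {
  hiddenDims <- as.integer(hiddenDims)
  if (length(hiddenDims) != 3L || any(hiddenDims < 1L))
    stop("'hiddenDims' must be three positive integers")
  if (!is.null(viewWeights) && abs(sum(viewWeights) - 1) > 1e-9)
    stop("'viewWeights' must sum to 1 (got ", sum(viewWeights), ")")
  if (epochs < 0) stop("'epochs' must be nonnegative")
  structure(list(hiddenDims = hiddenDims, activation = "sigmoid",
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 learningRate = learningRate, viewWeights = viewWeights,
                 seed = as.integer(seed)),
            class = "aeConfig")
}

#' Mean squared reconstruction error
#'
#' @param x,xHat numeric matrices of identical shape.
#' @return Mean over all entries of the squared difference.
#' @examples
#' mseLoss(matrix(1:3), matrix(c(2, 2, 5)))  # 5/3
#' @export
mseLoss <- function(x, xHat) {
  if (!identical(dim(x), dim(xHat)))
    stop("shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(xHat), collapse = "x"))
  mean((x - xHat)^2)
}

#' Per-view weighted autoencoder loss
#'
#' `a * mse(x1, xHat1) + b * mse(x2, xHat2) + c * mse(x3, xHat3)` with
#' nonnegative weights summing to 1: the convex combination of per-view mean
#' squared reconstruction errors.
#'
#' @param views list of view matrices.
#' @param recons list of reconstruction matrices, same shapes.
#' @param weights numeric vector on the simplex, one weight per view.
#' @return Nonnegative scalar loss.
#' @examples
#' x <- list(matrix(0, 2, 2), matrix(0, 2, 2), matrix(0, 2, 2))
#' r <- list(matrix(1, 2, 2), matrix(sqrt(2), 2, 2), matrix(sqrt(3), 2, 2))
#' weightedAELoss(x, r, c(0.4, 0.3, 0.3))  # 0.4*1 + 0.3*2 + 0.3*3 = 1.9
#' @export
weightedAELoss <- function(views, recons, weights) {
  if (length(views) != length(recons) || length(views) != length(weights))
    stop("'views', 'recons' and 'weights' must have equal length")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("'weights' must sum to 1 (got ", sum(weights), ")")
  sum(vapply(seq_along(views),
             function(i) weights[i] * mseLoss(views[[i]], recons[[i]]),
             numeric(1)))
}

# Per-feature min-max scaling to [0, 1]; constant features map to 0.5
# (mid-range, where the sigmoid decoder is least saturated).
minMaxScale <- function(m) {
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(m, 2L, lo, "-"), 2L, rng, "/")
  out[, const] <- 0.5
  out
}

aeForward <- function(X, par) {
  A1 <- sigmoid(sweep(X %*% par$W1, 2L, par$b1, "+"))
  A2 <- sigmoid(sweep(A1 %*% par$W2, 2L, par$b2, "+"))
  A3 <- sigmoid(sweep(A2 %*% par$W3, 2L, par$b3, "+"))
  A4 <- sigmoid(sweep(A3 %*% par$W4, 2L, par$b4, "+"))
  list(A1 = A1, A2 = A2, A3 = A3, A4 = A4)
}

#' Train the weighted autoencoder and extract latent features
#'
#' Concatenates the (per-feature min-max scaled) views into one input matrix,
#' trains a fully connected autoencoder with sigmoid activations on all
#' layers, Adam optimization, and a reconstruction loss that is the weighted
#' sum of per-view mean squared errors on the corresponding output slices.
#' Returns the middle-hidden-layer activations of every sample: the latent
#' node-feature matrix of the downstream graph classifier.
#'
#' @param views list of cleaned [OmicsView-class] objects aligned on sample
#'   ids (no missing values; run [preprocessView()] first).
#' @param cfg an [aeConfig()].
#' @return List with `latent` (a [LatentFeatures-class]), `lossTrace`
#'   (full-data weighted loss at the end of each epoch; empty when
#'   `epochs = 0`), and `params` (the trained weights).
#' @export
trainAutoencoder <- function(views, cfg = aeConfig()) {
  stopifnot(inherits(cfg, "aeConfig"), length(views) >= 1L)
  ids <- sampleIds(views[[1L]])
  for (v in views[-1L])
    if (!identical(sampleIds(v), ids))
      stop("views are not aligned on sample ids: '", viewName(v),
           "' differs from '", viewName(views[[1L]]), "'")
  for (v in views)
    if (anyNA(viewMatrix(v)))
      stop("view '", viewName(v), "' contains missing values; preprocess first")

  m <- length(views)
  weights <- cfg$viewWeights %||%
    (if (m == 3L) c(0.4, 0.3, 0.3) else rep(1 / m, m))
  if (length(weights) != m)
    stop("need one view weight per view (", m, " views, ",
         length(weights), " weights)")

  scaled <- lapply(views, function(v) minMaxScale(viewMatrix(v)))
  X <- do.call(cbind, scaled)
  n <- nrow(X); p <- ncol(X)
  pv <- vapply(scaled, ncol, integer(1))
  ends <- cumsum(pv)
  slices <- lapply(seq_len(m), function(i) (c(0L, ends)[i] + 1L):ends[i])
  dims <- c(p, cfg$hiddenDims, p)

  withr::with_seed(cfg$seed, {
    par <- list(W1 = glorot(dims[1], dims[2]), b1 = numeric(dims[2]),
                W2 = glorot(dims[2], dims[3]), b2 = numeric(dims[3]),
                W3 = glorot(dims[3], dims[4]), b3 = numeric(dims[4]),
                W4 = glorot(dims[4], dims[5]), b4 = numeric(dims[5]))
    opt <- adamInit(par, lr = cfg$learningRate)
    lossTrace <- numeric(0)
    # gradient scale per output column: weight_v * 2 / (batch * p_v)
    colScale <- numeric(p)
    for (i in seq_len(m)) colScale[slices[[i]]] <- 2 * weights[i] / pv[i]

    if (cfg$epochs > 0) {
      for (epoch in seq_len(cfg$epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = cfg$batchSize)
        for (s in starts) {
          idx <- ord[s:min(s + cfg$batchSize - 1L, n)]
          Xb <- X[idx, , drop = FALSE]
          fw <- aeForward(Xb, par)
          nb <- length(idx)
          dA4 <- sweep(fw$A4 - Xb, 2L, colScale / nb, "*")
          dZ4 <- dA4 * fw$A4 * (1 - fw$A4)
          dZ3 <- (dZ4 %*% t(par$W4)) * fw$A3 * (1 - fw$A3)
          dZ2 <- (dZ3 %*% t(par$W3)) * fw$A2 * (1 - fw$A2)
          dZ1 <- (dZ2 %*% t(par$W2)) * fw$A1 * (1 - fw$A1)
          grads <- list(W1 = crossprod(Xb, dZ1),    b1 = colSums(dZ1),
                        W2 = crossprod(fw$A1, dZ2), b2 = colSums(dZ2),
                        W3 = crossprod(fw$A2, dZ3), b3 = colSums(dZ3),
                        W4 = crossprod(fw$A3, dZ4), b4 = colSums(dZ4))
          st <- adamStep(opt, par, grads)
          opt <- st$state; par <- st$params
        }
        fw <- aeForward(X, par)
        loss <- weightedAELoss(lapply(slices, function(s) X[, s, drop = FALSE]),
                               lapply(slices, function(s) fw$A4[, s, drop = FALSE]),
                               weights)
        if (!is.finite(loss))
          stop(sprintf("non-finite autoencoder loss at epoch %d (lr = %g); inputs scaled to [0,1]?",
                       epoch, cfg$learningRate))
        lossTrace <- c(lossTrace, loss)
      }
    }
  })

  fw <- aeForward(X, par)
  latent <- fw$A2
  dimnames(latent) <- list(ids, paste0("L", seq_len(ncol(latent))))
  list(latent = new("LatentFeatures", matrix = latent),
       lossTrace = lossTrace, params = par)
}
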