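# Minimal Adam optimizer over a named list of numeric arrays.
# Weight decay is L2 added to the raw gradient (coupled, as in classic Adam).

adamInit <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                     weightDecay = 0) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, wd = weightDecay,
       t = 0L,
       m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))))
}

adamStep <- function(state, params, grads) {
  state$t <- state$t + 1L
  bc1 <- 1 - state$beta1^state$t
  bc2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (state$wd > 0) g <- g + state$wd * params[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      state$lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + state$eps)
  }
  list(state = state, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Glorot-uniform weight matrix; consumes the current RNG stream.
glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -l, l), nin, nout)
}

sigmoid <- function(z) 1 / (1 + exp(-z))
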