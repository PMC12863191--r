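# Minimal dense-network engine used by the VAE models: fully connected
# layers with batch normalization, ReLU and inverted dropout, trained by
# backpropagation with Adam.  Written on base-R matrix ops (BLAS-backed);
# shapes follow the "rows are samples" convention throughout.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
LOGVAR_CLAMP <- 15

# broadcast a length-n row vector over the rows of a B x n matrix
.addrow <- function(X, r) X + rep(r, each = nrow(X))
.mulrow <- function(X, r) X * rep(r, each = nrow(X))

# Xavier (Glorot) uniform initialization
dense_init <- function(n_in, n_out, bn = TRUE) {
  lim <- sqrt(6 / (n_in + n_out))
  l <- list(W = matrix(runif(n_in * n_out, -lim, lim), n_in, n_out),
            b = rep(0, n_out))
  if (bn) {
    l$gamma <- rep(1, n_out)
    l$beta <- rep(0, n_out)
    l$run_mean <- rep(0, n_out)
    l$run_var <- rep(1, n_out)
  }
  l
}

# forward through FC (+ BN + ReLU + dropout when configured); returns the
# output and, in training mode, the cache needed for the backward pass
dense_forward <- function(layer, X, train = FALSE, dropout = 0,
                          activation = c("relu", "none")) {
  activation <- match.arg(activation)
  A <- .addrow(X %*% layer$W, layer$b)
  cache <- list(X = X)
  H <- A
  if (!is.null(layer$gamma)) {
    use_batch <- train && nrow(A) > 1L
    if (use_batch) {
      mu <- colMeans(A)
      v <- colMeans(.addrow(A, -mu)^2)
      layer$run_mean <- (1 - BN_MOMENTUM) * layer$run_mean + BN_MOMENTUM * mu
      layer$run_var <- (1 - BN_MOMENTUM) * layer$run_var + BN_MOMENTUM * v
    } else {
      mu <- layer$run_mean
      v <- layer$run_var
    }
    invstd <- 1 / sqrt(v + BN_EPS)
    Hn <- .mulrow(.addrow(A, -mu), invstd)
    H <- .addrow(.mulrow(Hn, layer$gamma), layer$beta)
    cache$Hn <- Hn
    cache$invstd <- invstd
    cache$batch_stats <- use_batch
  }
  if (activation == "relu") {
    mask <- H > 0
    H <- H * mask
    cache$relu <- mask
  }
  if (train && dropout > 0) {
    keep <- 1 - dropout
    dmask <- (matrix(runif(length(H)), nrow(H)) < keep) / keep
    H <- H * dmask
    cache$drop <- dmask
  }
  list(out = H, cache = cache, layer = layer)
}

# backward pass; returns parameter gradients and the gradient w.r.t. X
dense_backward <- function(layer, cache, dOut) {
  if (!is.null(cache$drop)) dOut <- dOut * cache$drop
  if (!is.null(cache$relu)) dOut <- dOut * cache$relu
  g <- list()
  if (!is.null(layer$gamma)) {
    g$gamma <- colSums(dOut * cache$Hn)
    g$beta <- colSums(dOut)
    dHn <- .mulrow(dOut, layer$gamma)
    if (isTRUE(cache$batch_stats)) {
      B <- nrow(dHn)
      dA <- .mulrow(
        dHn - rep(colMeans(dHn), each = B) -
          cache$Hn * rep(colMeans(dHn * cache$Hn), each = B),
        cache$invstd)
    } else {
      dA <- .mulrow(dHn, cache$invstd)
    }
  } else {
    dA <- dOut
  }
  g$W <- crossprod(cache$X, dA)
  g$b <- colSums(dA)
  list(grads = g, dX = tcrossprod(dA, layer$W))
}

# ---- Adam -------------------------------------------------------------

TRAINABLE <- c("W", "b", "gamma", "beta")

adam_init <- function(params) {
  walk <- function(p) {
    if (is.list(p) && any(names(p) %in% TRAINABLE)) {
      out <- list()
      for (nm in intersect(names(p), TRAINABLE))
        out[[nm]] <- list(m = p[[nm]] * 0, v = p[[nm]] * 0)
      for (nm in setdiff(names(p), c(TRAINABLE, "run_mean", "run_var")))
        out[[nm]] <- walk(p[[nm]])
      out
    } else if (is.list(p)) {
      lapply(p, walk)
    } else NULL
  }
  list(t = 0L, s = walk(params))
}

# one Adam step over a nested parameter list; weight decay (L2) applied to
# weight matrices only
adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  walk <- function(p, g, s) {
    if (is.null(g)) return(list(p = p, s = s))
    if (is.list(p) && any(names(p) %in% TRAINABLE)) {
      for (nm in intersect(names(g), TRAINABLE)) {
        gr <- g[[nm]]
        if (nm == "W" && weight_decay > 0) gr <- gr + weight_decay * p[[nm]]
        s[[nm]]$m <- beta1 * s[[nm]]$m + (1 - beta1) * gr
        s[[nm]]$v <- beta2 * s[[nm]]$v + (1 - beta2) * gr^2
        mh <- s[[nm]]$m / (1 - beta1^t)
        vh <- s[[nm]]$v / (1 - beta2^t)
        p[[nm]] <- p[[nm]] - lr * mh / (sqrt(vh) + eps)
      }
      for (nm in setdiff(names(g), TRAINABLE)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else if (is.list(p)) {
      for (nm in names(g)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else list(p = p, s = s)
  }
  r <- walk(params, grads, state$s)
  state$s <- r$s
  list(params = r$p, state = state)
}

# number of trainable parameters in a nested parameter structure
param_count <- function(params) {
  if (!is.list(params)) return(length(params))
  keep <- setdiff(names(params), c("run_mean", "run_var"))
  if (is.null(names(params))) keep <- seq_along(params)
  sum(vapply(params[keep], param_count, numeric(1)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
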