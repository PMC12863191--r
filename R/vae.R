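#' Fit a window-based variational autoencoder to a haplotype panel
#'
#' The model cuts the `d` SNPs into consecutive windows of `window_size`
#' sites and fits one encoder/decoder pair per window.  Each encoder is a
#' three-hidden-layer dense network (batch normalization and ReLU after
#' every hidden layer, inverted dropout) emitting a `bottleneck`-dimensional
#' Gaussian mean and log-variance; the decoder mirrors it and emits
#' per-site Bernoulli probabilities through a sigmoid.  Training maximises
#' the evidence lower bound: summed binary cross-entropy plus `beta_kl`
#' times the closed-form KL divergence to the isotropic Gaussian prior,
#' with Xavier initialization, the Adam optimizer and a
#' reduce-on-plateau learning-rate schedule.
#'
#' Three conditioning regimes are available:
#' \describe{
#'   \item{`"none"`}{one unconditional VAE over all populations.}
#'   \item{`"cvae"`}{a one-hot population label is appended to the inputs of
#'     both the encoder and the decoder.}
#'   \item{`"yvae"`}{a bank of per-population VAEs, one full model fit to
#'     each population separately (so the bank has `|Y|` times the
#'     parameters of a single model).}
#' }
#'
#' With `use_vq = TRUE` the Gaussian bottleneck is replaced by a
#' vector-quantized one: the pre-bottleneck activation passes through a
#' `tanh`, is split into `heads` sub-vectors, and each is snapped to its
#' nearest codebook embedding.  Gradients cross the non-differentiable
#' quantizer via the straight-through estimator, and the objective adds the
#' codebook (embedding) and commitment terms to the reconstruction loss.
#'
#' @param panel a [genotype_panel()] of training haplotypes.
#' @param window_size SNPs per window; `NULL` (default) uses a single
#'   window spanning all `d` sites.
#' @param bottleneck latent dimensions per window (the total latent
#'   dimension is `ceiling(d / window_size) * bottleneck`).
#' @param hidden sizes of the three hidden layers (encoder order; the
#'   decoder mirrors them).
#' @param dropout dropout rate in all hidden layers (default 0.5).
#' @param conditioning `"none"`, `"cvae"` or `"yvae"`.
#' @param use_vq replace the Gaussian bottleneck by a vector-quantized one.
#' @param heads number of quantizer heads per window (`bottleneck` must be
#'   divisible by `heads`); ignored unless `use_vq`.
#' @param codebook_size number of codebook embeddings `K` (ignored unless
#'   `use_vq`).
#' @param commit_weight weight of the commitment loss (default 1).
#' @param beta_kl weight of the KL term (default 1, the plain ELBO).
#' @param learning_rate Adam step size; default 0.025 for VQ training and
#'   1e-3 otherwise.
#' @param weight_decay L2 penalty on weight matrices; default 0.01 for VQ
#'   training and 0 otherwise.
#' @param plateau_factor multiply the learning rate by this factor when the
#'   training loss stagnates (default 0.1).
#' @param patience epochs without improvement before the learning rate is
#'   reduced (default 5).
#' @param epochs maximum training epochs (default 100; `epochs = 0` returns
#'   an initialized, untrained model).
#' @param batch_size minibatch size (default 128).
#' @param seed integer seed controlling initialization, shuffling, dropout
#'   and the reparametrization noise; identical seeds give identical fits.
#' @param verbose print the per-epoch loss.
#' @return An object of class `snp_vae`.
#' @seealso [predict.snp_vae()], [encode()], [decode()], [compress()],
#'   [classify_map()], [sample_conditional()]
#' @export
snp_vae <- function(panel,
                    window_size = NULL,
                    bottleneck = 8,
                    hidden = c(256, 128, 64),
                    dropout = 0.5,
                    conditioning = c("none", "cvae", "yvae"),
                    use_vq = FALSE,
                    heads = 1,
                    codebook_size = 64,
                    commit_weight = 1,
                    beta_kl = 1,
                    learning_rate = NULL,
                    weight_decay = NULL,
                    plateau_factor = 0.1,
                    patience = 5,
                    epochs = 100,
                    batch_size = 128,
                    seed = 1L,
                    verbose = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  conditioning <- match.arg(conditioning)
  if (is.null(learning_rate)) learning_rate <- if (use_vq) 0.025 else 1e-3
  if (is.null(weight_decay)) weight_decay <- if (use_vq) 0.01 else 0
  d <- ncol(panel$haplotypes)
  if (is.null(window_size)) window_size <- d
  stopifnot(window_size >= 1, bottleneck >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, length(hidden) == 3)
  if (use_vq && bottleneck %% heads != 0)
    stop("'bottleneck' must be divisible by 'heads'")
  labels <- sort(unique(panel$populations))
  cfg <- list(window_size = as.integer(window_size),
              bottleneck = as.integer(bottleneck),
              hidden = as.integer(hidden), dropout = dropout,
              conditioning = conditioning, use_vq = use_vq,
              heads = as.integer(heads),
              codebook_size = as.integer(codebook_size),
              commit_weight = commit_weight, beta_kl = beta_kl,
              learning_rate = learning_rate, weight_decay = weight_decay,
              plateau_factor = plateau_factor, patience = as.integer(patience),
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              seed = as.integer(seed))

  if (conditioning == "yvae") {
    bank <- list()
    for (i in seq_along(labels)) {
      k <- labels[i]
      sub <- panel[panel$populations == k]
      if (nrow(sub$haplotypes) == 0L)
        stop(sprintf("population '%s' has no training haplotypes", k))
      if (verbose) message("Y-VAE: fitting population ", k)
      bank[[k]] <- fit_vae(sub, modifyList(cfg, list(
        conditioning = "none", seed = cfg$seed + i - 1L)), labels = k,
        verbose = verbose)
    }
    model <- structure(
      list(config = cfg, d = d, positions = panel$positions,
           labels = labels, bank = bank,
           loss_history = do.call(rbind, lapply(labels, function(k) {
             h <- bank[[k]]$loss_history
             if (nrow(h)) cbind(population = k, h) else NULL
           }))),
      class = "snp_vae")
    return(model)
  }
  fit_vae(panel, cfg, labels = labels, verbose = verbose)
}

# ---- internal fitting -------------------------------------------------

make_windows <- function(d, w) {
  starts <- seq(1L, d, by = w)
  data.frame(start = starts, end = pmin(starts + w - 1L, d))
}

new_window_net <- function(w_in, cfg, cond_dim) {
  h <- cfg$hidden
  b <- cfg$bottleneck
  enc <- list(l1 = dense_init(w_in + cond_dim, h[1]),
              l2 = dense_init(h[1], h[2]),
              l3 = dense_init(h[2], h[3]))
  if (cfg$use_vq) {
    enc$z <- dense_init(h[3], b, bn = FALSE)
  } else {
    enc$mu <- dense_init(h[3], b, bn = FALSE)
    enc$lv <- dense_init(h[3], b, bn = FALSE)
    # start with small posterior noise (sigma ~ exp(-2)); the KL term grows
    # sigma back toward the prior for uninformative dimensions, while wide
    # bottlenecks are not swamped by reparametrization noise early on
    enc$lv$b <- rep(-4, b)
  }
  dec <- list(l1 = dense_init(b + cond_dim, h[3]),
              l2 = dense_init(h[3], h[2]),
              l3 = dense_init(h[2], h[1]),
              out = dense_init(h[1], w_in, bn = FALSE))
  list(enc = enc, dec = dec)
}

fit_vae <- function(panel, cfg, labels, verbose = FALSE) {
  local_rng(cfg$seed)
  X <- panel$haplotypes
  storage.mode(X) <- "double"
  n <- nrow(X); d <- ncol(X)
  windows <- make_windows(d, cfg$window_size)
  cond_dim <- if (cfg$conditioning == "cvae") length(labels) else 0L
  nets <- lapply(seq_len(nrow(windows)), function(j)
    new_window_net(windows$end[j] - windows$start[j] + 1L, cfg, cond_dim))
  codebook <- if (cfg$use_vq)
    matrix(runif(cfg$codebook_size * cfg$bottleneck %/% cfg$heads, -1, 1),
           cfg$codebook_size) else NULL
  model <- structure(
    list(config = cfg, d = d, positions = panel$positions, labels = labels,
         windows = windows, nets = nets, codebook = codebook,
         loss_history = data.frame()),
    class = "snp_vae")
  if (cfg$epochs == 0L) return(model)

  C_all <- if (cond_dim) onehot(panel$populations, labels) else NULL
  opt <- lapply(nets, adam_init)
  opt_cb <- if (cfg$use_vq) adam_init(list(list(W = codebook))) else NULL
  lr <- cfg$learning_rate
  best <- Inf; wait <- 0L
  hist <- vector("list", cfg$epochs)

  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    tot <- c(bce = 0, kl = 0, vq_embed = 0, vq_commit = 0)
    for (bs in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      Cb <- if (cond_dim) C_all[bs, , drop = FALSE] else NULL
      for (j in seq_len(nrow(windows))) {
        Xw <- X[bs, windows$start[j]:windows$end[j], drop = FALSE]
        st <- train_step_window(model$nets[[j]], model$codebook, Xw, Cb, cfg)
        up <- adam_step(st$net, st$grads, opt[[j]], lr, cfg$weight_decay)
        model$nets[[j]] <- up$params
        opt[[j]] <- up$state
        if (cfg$use_vq && !is.null(st$grad_cb)) {
          upc <- adam_step(list(list(W = model$codebook)),
                           list(list(W = st$grad_cb)), opt_cb, lr, 0)
          model$codebook <- upc$params[[1]]$W
          opt_cb <- upc$state
        }
        tot <- tot + st$loss * length(bs)
      }
    }
    tot <- tot / n
    total <- tot[["bce"]] + cfg$beta_kl * tot[["kl"]] + tot[["vq_embed"]] +
      cfg$commit_weight * tot[["vq_commit"]]
    hist[[ep]] <- data.frame(epoch = ep, total = total, bce = tot[["bce"]],
                             kl = tot[["kl"]], vq_embed = tot[["vq_embed"]],
                             vq_commit = tot[["vq_commit"]], lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  bce %.4f  lr %.2g",
                      ep, total, tot[["bce"]], lr))
    if (total < best - 1e-6) { best <- total; wait <- 0L }
    else {
      wait <- wait + 1L
      if (wait >= cfg$patience) { lr <- lr * cfg$plateau_factor; wait <- 0L }
    }
  }
  model$loss_history <- do.call(rbind, hist)
  model
}

# forward + backward + losses for one window on one minibatch
train_step_window <- function(net, codebook, Xw, Cb, cfg) {
  B <- nrow(Xw)
  U <- if (is.null(Cb)) Xw else cbind(Xw, Cb)
  f1 <- dense_forward(net$enc$l1, U, TRUE, cfg$dropout)
  net$enc$l1 <- f1$layer
  f2 <- dense_forward(net$enc$l2, f1$out, TRUE, cfg$dropout)
  net$enc$l2 <- f2$layer
  f3 <- dense_forward(net$enc$l3, f2$out, TRUE, cfg$dropout)
  net$enc$l3 <- f3$layer
  loss <- c(bce = 0, kl = 0, vq_embed = 0, vq_commit = 0)
  grad_cb <- NULL
  if (cfg$use_vq) {
    fz <- dense_forward(net$enc$z, f3$out, activation = "none")
    Z <- tanh(fz$out)
    qz <- quantize_batch(Z, codebook, cfg$heads)
    Q <- qz$quantized
    Vd <- if (is.null(Cb)) Q else cbind(Q, Cb)
    loss[["vq_embed"]] <- sum((Q - Z)^2) / B
    loss[["vq_commit"]] <- loss[["vq_embed"]]
  } else {
    fmu <- dense_forward(net$enc$mu, f3$out, activation = "none")
    flv <- dense_forward(net$enc$lv, f3$out, activation = "none")
    M <- fmu$out
    L <- pmin(pmax(flv$out, -LOGVAR_CLAMP), LOGVAR_CLAMP)
    sig <- exp(0.5 * L)
    eps <- matrix(rnorm(length(M)), nrow(M))
    Z <- M + sig * eps
    Vd <- if (is.null(Cb)) Z else cbind(Z, Cb)
    loss[["kl"]] <- 0.5 * sum(M^2 + exp(L) - L - 1) / B
  }
  g1 <- dense_forward(net$dec$l1, Vd, TRUE, cfg$dropout)
  net$dec$l1 <- g1$layer
  g2 <- dense_forward(net$dec$l2, g1$out, TRUE, cfg$dropout)
  net$dec$l2 <- g2$layer
  g3 <- dense_forward(net$dec$l3, g2$out, TRUE, cfg$dropout)
  net$dec$l3 <- g3$layer
  go <- dense_forward(net$dec$out, g3$out, activation = "none")
  O <- go$out
  # numerically stable summed BCE from logits
  loss[["bce"]] <- sum(pmax(O, 0) - O * Xw + log1p(exp(-abs(O)))) / B

  P <- sigmoid(O)
  dO <- (P - Xw) / B
  bo <- dense_backward(net$dec$out, go$cache, dO)
  b3 <- dense_backward(net$dec$l3, g3$cache, bo$dX)
  b2 <- dense_backward(net$dec$l2, g2$cache, b3$dX)
  b1 <- dense_backward(net$dec$l1, g1$cache, b2$dX)
  dV <- b1$dX
  b <- cfg$bottleneck
  dZdec <- dV[, seq_len(b), drop = FALSE]
  grads <- list(enc = list(), dec = list(out = bo$grads, l3 = b3$grads,
                                         l2 = b2$grads, l1 = b1$grads))
  if (cfg$use_vq) {
    # straight-through: decoder gradient copied to z; plus commitment pull
    dZ <- dZdec + 2 * cfg$commit_weight * (Z - qz$quantized) / B
    dT <- dZ * (1 - Z^2)
    bz <- dense_backward(net$enc$z, fz$cache, dT)
    grads$enc$z <- bz$grads
    dh3 <- bz$dX
    # embedding loss moves assigned codebook rows toward encoder outputs
    grad_cb <- matrix(0, nrow(codebook), ncol(codebook))
    qh <- ncol(codebook)
    for (h in seq_len(cfg$heads)) {
      cols <- ((h - 1L) * qh + 1L):(h * qh)
      dE <- 2 * (qz$quantized[, cols, drop = FALSE] -
                   Z[, cols, drop = FALSE]) / B
      agg <- rowsum(dE, qz$indices[, h])
      grad_cb[as.integer(rownames(agg)), ] <-
        grad_cb[as.integer(rownames(agg)), ] + agg
    }
  } else {
    dM <- dZdec + cfg$beta_kl * M / B
    dL <- dZdec * eps * 0.5 * sig + cfg$beta_kl * 0.5 * (exp(L) - 1) / B
    bmu <- dense_backward(net$enc$mu, fmu$cache, dM)
    blv <- dense_backward(net$enc$lv, flv$cache, dL)
    grads$enc$mu <- bmu$grads
    grads$enc$lv <- blv$grads
    dh3 <- bmu$dX + blv$dX
  }
  e3 <- dense_backward(net$enc$l3, f3$cache, dh3)
  e2 <- dense_backward(net$enc$l2, f2$cache, e3$dX)
  e1 <- dense_backward(net$enc$l1, f1$cache, e2$dX)
  grads$enc$l3 <- e3$grads
  grads$enc$l2 <- e2$grads
  grads$enc$l1 <- e1$grads
  list(net = net, grads = grads, grad_cb = grad_cb, loss = loss)
}

onehot <- function(labels, label_set) {
  idx <- match(labels, label_set)
  if (anyNA(idx))
    stop(sprintf("label(s) not in the model's label set: %s",
                 paste(unique(labels[is.na(idx)]), collapse = ", ")))
  C <- matrix(0, length(labels), length(label_set))
  C[cbind(seq_along(idx), idx)] <- 1
  C
}

# ---- deterministic encode / decode ------------------------------------

as_hap_matrix <- function(x, d = NULL) {
  if (inherits(x, "genotype_panel")) x <- x$haplotypes
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!is.null(d) && ncol(x) != d)
    stop(sprintf("input has %d SNPs but the model expects d = %d",
                 ncol(x), d))
  x
}

resolve_labels <- function(model, x, label, n) {
  mode <- model$config$conditioning
  if (mode == "none") return(NULL)
  if (is.null(label)) {
    if (inherits(x, "genotype_panel")) label <- x$populations
    else stop(sprintf("conditioning mode '%s' requires a population label",
                      mode))
  }
  rep(as.character(label), length.out = n)
}

#' Encode haplotypes into latent Gaussian statistics
#'
#' Runs the encoder in evaluation mode (no dropout, batch-norm running
#' statistics) and returns the latent mean and standard deviation.  The
#' per-window statistics are concatenated window-major, giving
#' `q = ceiling(d / w) * b` latent dimensions.
#'
#' @param model a fitted [snp_vae()].
#' @param x a [genotype_panel()], a 0/1 matrix (rows are haplotypes) or a
#'   single 0/1 vector of length `d`.
#' @param label population label(s); required for `"cvae"` and `"yvae"`
#'   conditioning (taken from the panel when `x` is one).
#' @return A list of class `latent_stats` with elements `mu`, `sigma` and
#'   `logvar` (vectors for a single haplotype, row-matrices otherwise).
#' @export
encode <- function(model, x, label = NULL) {
  stopifnot(inherits(model, "snp_vae"))
  single <- is.vector(x) && !inherits(x, "genotype_panel")
  X <- as_hap_matrix(x, model$d)
  labs <- resolve_labels(model, x, label, nrow(X))
  if (model$config$conditioning == "yvae") {
    out <- encode_bank(model, X, labs)
  } else {
    out <- encode_matrix(model, X,
                         if (is.null(labs)) NULL else onehot(labs, model$labels))
  }
  if (single) out <- lapply(out, drop)
  structure(out, class = "latent_stats")
}

encode_bank <- function(model, X, labs) {
  q <- total_latent_dim(model)
  mu <- matrix(0, nrow(X), q); lv <- matrix(0, nrow(X), q)
  for (k in unique(labs)) {
    sub <- model$bank[[k]]
    if (is.null(sub)) stop(sprintf("label '%s' is not in the Y-VAE bank", k))
    i <- which(labs == k)
    o <- encode_matrix(sub, X[i, , drop = FALSE], NULL)
    mu[i, ] <- o$mu; lv[i, ] <- o$logvar
  }
  list(mu = mu, sigma = exp(0.5 * lv), logvar = lv)
}

encode_matrix <- function(model, X, C) {
  cfg <- model$config
  b <- cfg$bottleneck
  q <- nrow(model$windows) * b
  MU <- matrix(0, nrow(X), q); LV <- matrix(0, nrow(X), q)
  for (j in seq_len(nrow(model$windows))) {
    Xw <- X[, model$windows$start[j]:model$windows$end[j], drop = FALSE]
    U <- if (is.null(C)) Xw else cbind(Xw, C)
    net <- model$nets[[j]]
    h <- dense_forward(net$enc$l3,
           dense_forward(net$enc$l2,
             dense_forward(net$enc$l1, U)$out)$out)$out
    cols <- ((j - 1L) * b + 1L):(j * b)
    if (cfg$use_vq) {
      MU[, cols] <- tanh(dense_forward(net$enc$z, h, activation = "none")$out)
      LV[, cols] <- -Inf
    } else {
      MU[, cols] <- dense_forward(net$enc$mu, h, activation = "none")$out
      LV[, cols] <- pmin(pmax(
        dense_forward(net$enc$lv, h, activation = "none")$out,
        -LOGVAR_CLAMP), LOGVAR_CLAMP)
    }
  }
  list(mu = MU, sigma = exp(0.5 * LV), logvar = LV)
}

#' Reparametrize latent statistics into a latent sample
#'
#' The reparametrization trick: `z = mu + sigma * epsilon` elementwise,
#' with `epsilon` drawn from a standard Gaussian when not supplied.
#'
#' @param stats a `latent_stats` object (or any list with `mu` and `sigma`).
#' @param epsilon noise of the same shape as `mu`; defaults to
#'   `rnorm` draws.
#' @return The latent representation `z`, same shape as `mu`.
#' @export
reparameterize <- function(stats, epsilon = NULL) {
  mu <- stats$mu; sigma <- stats$sigma
  if (is.null(epsilon)) epsilon <- array(rnorm(length(mu)), dim(mu) %||% length(mu))
  if (length(epsilon) != length(mu)) stop("'epsilon' shape does not match 'mu'")
  mu + sigma * epsilon
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decode latent vectors into Bernoulli probabilities and bits
#'
#' Runs the decoder in evaluation mode and binarizes the sigmoid output
#' with the unit step at 1/2 (ties, `o == 0.5`, map to 1).
#'
#' @param model a fitted [snp_vae()].
#' @param z latent vector of length `q`, or a matrix with `q` columns.
#' @param label population label(s) for conditioned models.
#' @return A list of class `snp_reconstruction` with `prob` (in `[0, 1]`)
#'   and `bits` (0/1).
#' @export
decode <- function(model, z, label = NULL) {
  stopifnot(inherits(model, "snp_vae"))
  single <- is.vector(z)
  if (single) z <- matrix(z, nrow = 1)
  q <- total_latent_dim(model)
  if (ncol(z) != q)
    stop(sprintf("latent input has %d dimensions but the model expects q = %d",
                 ncol(z), q))
  labs <- resolve_labels(model, NULL, label, nrow(z))
  if (model$config$conditioning == "yvae") {
    P <- matrix(0, nrow(z), model$d)
    for (k in unique(labs)) {
      sub <- model$bank[[k]]
      if (is.null(sub)) stop(sprintf("label '%s' is not in the Y-VAE bank", k))
      i <- which(labs == k)
      P[i, ] <- decode_matrix(sub, z[i, , drop = FALSE], NULL)
    }
  } else {
    P <- decode_matrix(model, z,
                       if (is.null(labs)) NULL else onehot(labs, model$labels))
  }
  out <- list(prob = if (single) drop(P) else P,
              bits = binarize(if (single) drop(P) else P))
  structure(out, class = "snp_reconstruction")
}

#' @rdname decode
#' @param o Bernoulli probabilities to binarize.
#' @export
binarize <- function(o) {
  b <- as.integer(o >= 0.5)
  dim(b) <- dim(o)
  b
}

decode_matrix <- function(model, z, C) {
  b <- model$config$bottleneck
  P <- matrix(0, nrow(z), model$d)
  for (j in seq_len(nrow(model$windows))) {
    cols <- ((j - 1L) * b + 1L):(j * b)
    V <- z[, cols, drop = FALSE]
    if (!is.null(C)) V <- cbind(V, C)
    net <- model$nets[[j]]
    h <- dense_forward(net$dec$l3,
           dense_forward(net$dec$l2,
             dense_forward(net$dec$l1, V)$out)$out)$out
    O <- dense_forward(net$dec$out, h, activation = "none")$out
    P[, model$windows$start[j]:model$windows$end[j]] <- sigmoid(O)
  }
  P
}

total_latent_dim <- function(model) {
  if (model$config$conditioning == "yvae")
    return(total_latent_dim(model$bank[[1]]))
  nrow(model$windows) * model$config$bottleneck
}

# quantizer heads across all windows (latent layout is window-major, so the
# full-width latent splits into heads * n_windows consecutive head slices)
total_heads <- function(model) nrow(model$windows) * model$config$heads

#' Evidence-lower-bound loss breakdown
#'
#' Summed binary cross-entropy between the binary input and the decoder
#' probabilities, plus the closed-form Gaussian KL divergence
#' `0.5 * sum(mu^2 + sigma^2 - log sigma^2 - 1)` to the isotropic prior.
#' Probabilities are clamped to `[exp(-100), 1 - exp(-100)]` before the
#' logarithms, so the loss is always finite.
#'
#' @param x binary vector (or matrix) of true bits.
#' @param recon an [decode()] result, or a probability vector/matrix.
#' @param stats a `latent_stats` object; omit for a reconstruction-only
#'   breakdown.
#' @param beta_kl KL weight (default 1).
#' @return A list of class `loss_breakdown` with `bce`, `kl`, `vq_embed`,
#'   `vq_commit` and `total = bce + beta_kl * kl + vq_embed +
#'   commit_weight * vq_commit` (sums over all supplied samples).
#' @export
elbo_loss <- function(x, recon, stats = NULL, beta_kl = 1) {
  o <- if (inherits(recon, "snp_reconstruction")) recon$prob else recon
  if (length(o) != length(x)) stop("'x' and the reconstruction differ in shape")
  if (anyNA(o)) stop("reconstruction probabilities contain NA")
  bce <- bce_sum(x, o)
  kl <- 0
  if (!is.null(stats)) {
    lv <- stats$logvar %||% log(stats$sigma^2)
    kl <- 0.5 * sum(stats$mu^2 + exp(lv) - lv - 1)
  }
  structure(list(bce = bce, kl = kl, vq_embed = 0, vq_commit = 0,
                 total = bce + beta_kl * kl),
            class = "loss_breakdown")
}

# summed BCE with probability clamping (log terms floored at -100, so an
# exact 0/1 probability never yields -Inf or 0 * Inf)
bce_sum <- function(x, o) {
  lo <- pmax(log(o), -100)
  l1o <- pmax(log1p(-o), -100)
  -sum(x * lo + (1 - x) * l1o)
}

# ---- S3 methods -------------------------------------------------------

#' @export
print.snp_vae <- function(x, ...) {
  cfg <- x$config
  kind <- if (cfg$use_vq) "VQ-VAE" else "VAE"
  cond <- switch(cfg$conditioning, none = "unconditional",
                 cvae = "one-hot conditioned (C-VAE)",
                 yvae = sprintf("per-population bank (Y-VAE, %d populations)",
                                length(x$labels)))
  cat(sprintf("%s for %d-SNP haplotypes, %s\n", kind, x$d, cond))
  if (cfg$conditioning != "yvae")
    cat(sprintf("windows: %d x %d SNPs; latent: %d per window (q = %d)\n",
                nrow(x$windows), cfg$window_size, cfg$bottleneck,
                total_latent_dim(x)))
  if (cfg$use_vq)
    cat(sprintf("codebook: %d embeddings x %d dims, %d head(s)\n",
                cfg$codebook_size, cfg$bottleneck %/% cfg$heads, cfg$heads))
  hist <- x$loss_history
  if (!is.null(hist) && NROW(hist) > 0)
    cat(sprintf("trained %d epochs; final loss %.4f\n",
                max(hist$epoch), hist$total[nrow(hist)]))
  else cat("untrained (initialized only)\n")
  cat(sprintf("parameters: %s\n", format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.snp_vae <- function(object, ...) {
  print(object)
  hist <- object$loss_history
  if (!is.null(hist) && NROW(hist) > 0) {
    cat("\nloss history (last 5 epochs):\n")
    print(utils::tail(hist, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Number of trainable parameters of a model
#'
#' @param model a [snp_vae()] (a Y-VAE bank counts all its sub-models) or
#'   [snp_pca()] fit.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  UseMethod("n_parameters")
}

#' @export
n_parameters.snp_vae <- function(model) {
  if (model$config$conditioning == "yvae")
    return(sum(vapply(model$bank, n_parameters, numeric(1))))
  n <- sum(vapply(model$nets, param_count, numeric(1)))
  if (!is.null(model$codebook)) n <- n + length(model$codebook)
  n
}

#' Predict method for SNP VAEs
#'
#' Deterministic evaluation-mode pass through the model: encode to the
#' latent mean (or quantized code), decode, and binarize.
#'
#' @param object a fitted [snp_vae()].
#' @param newdata a [genotype_panel()], 0/1 matrix, or single haplotype.
#' @param type `"reconstruction"` (0/1 bits), `"prob"` (Bernoulli
#'   probabilities), `"latent"` (latent mean, quantized for VQ models) or
#'   `"stats"` (full `latent_stats`).
#' @param label population label(s) for conditioned models.
#' @param ... unused.
#' @return Per `type`; rows align with `newdata`.
#' @export
predict.snp_vae <- function(object, newdata,
                            type = c("reconstruction", "prob", "latent",
                                     "stats"),
                            label = NULL, ...) {
  type <- match.arg(type)
  single <- is.vector(newdata) && !inherits(newdata, "genotype_panel")
  X <- as_hap_matrix(newdata, object$d)
  labs <- resolve_labels(object, newdata, label, nrow(X))
  st <- encode(object, X, labs)
  Zs <- st$mu
  if (single) Zs <- matrix(Zs, nrow = 1)
  if (object$config$use_vq && object$config$conditioning != "yvae") {
    Zs <- quantize_batch(Zs, object$codebook, total_heads(object))$quantized
  } else if (object$config$use_vq) {
    for (k in unique(labs)) {
      i <- which(labs == k)
      sub <- object$bank[[k]]
      Zs[i, ] <- quantize_batch(Zs[i, , drop = FALSE], sub$codebook,
                                total_heads(sub))$quantized
    }
  }
  if (type == "latent") return(if (single) drop(Zs) else Zs)
  if (type == "stats") return(st)
  rec <- decode(object, if (single) drop(Zs) else Zs, labs)
  if (type == "prob") rec$prob else rec$bits
}

#' Reconstruction residuals of a model on a panel
#'
#' @param object a fitted [snp_vae()].
#' @param newdata panel, matrix or haplotype to reconstruct (required).
#' @param label population label(s) for conditioned models.
#' @param ... unused.
#' @return 0/1 residual (XOR of input and binarized reconstruction), same
#'   shape as the input.
#' @export
residuals.snp_vae <- function(object, newdata, label = NULL, ...) {
  xhat <- predict(object, newdata, type = "reconstruction", label = label)
  x <- as_hap_matrix(newdata, object$d)
  if (is.vector(xhat)) x <- drop(x)
  r <- abs(x - xhat)
  storage.mode(r) <- "integer"
  r
}

#' Plot the 2-D latent map of a panel
#'
#' Scatter of the first two latent dimensions of the encoded panel,
#' coloured by population label.
#'
#' @param x a fitted [snp_vae()].
#' @param panel a [genotype_panel()] to project.
#' @param dims which two latent dimensions to draw.
#' @param ... passed to [graphics::plot()].
#' @export
plot.snp_vae <- function(x, panel, dims = c(1, 2), ...) {
  st <- encode(x, panel)
  Z <- st$mu[, dims, drop = FALSE]
  pops <- factor(panel$populations)
  graphics::plot(Z[, 1], Z[, 2], col = as.integer(pops), pch = 19,
                 xlab = sprintf("latent dim %d", dims[1]),
                 ylab = sprintf("latent dim %d", dims[2]), ...)
  graphics::legend("topright", legend = levels(pops),
                   col = seq_along(levels(pops)), pch = 19, cex = 0.8)
  invisible(Z)
}

# ---- persistence ------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Checkpoints are self-describing (config plus weights) and reload
#' bit-exactly: a reloaded model produces identical reconstructions.
#'
#' @param model a [snp_vae()] or [snp_pca()] object.
#' @param path checkpoint file.
#' @return `load_model()` returns the model; `save_model()` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "snp_vae") || inherits(model, "snp_pca"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("checkpoint not found: %s", path))
  m <- readRDS(path)
  if (!inherits(m, "snp_vae") && !inherits(m, "snp_pca"))
    stop(sprintf("'%s' is not a genolatent model checkpoint", path))
  m
}

#' Fingerprint of a model's weights
#'
#' A digest over all parameters; compression archives embed it so that
#' decompression with a different model fails loudly instead of silently
#' returning wrong haplotypes.
#'
#' @param model a [snp_vae()] or [snp_pca()] object.
#' @return A character hash.
#' @export
model_fingerprint <- function(model) {
  UseMethod("model_fingerprint")
}

#' @export
model_fingerprint.snp_vae <- function(model) {
  digest::digest(model[c("nets", "codebook", "bank", "d")], algo = "xxhash64")
}
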