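# Vector quantization: multihead codebook lookup with exact
# nearest-neighbour assignment and the straight-through training contract
# (the gradient pathway lives in train_step_window()).

# quantize a B x b latent block: columns are split into `heads` consecutive
# sub-vectors, each snapped to its nearest codebook row (squared Euclidean
# distance, ties to the lowest index)
quantize_batch <- function(Z, codebook, heads) {
  if (is.null(codebook) || nrow(codebook) == 0L) stop("empty codebook")
  qh <- ncol(codebook)
  if (ncol(Z) != heads * qh)
    stop(sprintf("latent width %d does not match %d head(s) of dimension %d",
                 ncol(Z), heads, qh))
  idx <- matrix(0L, nrow(Z), heads)
  Q <- Z
  cb2 <- rowSums(codebook^2)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * qh + 1L):(h * qh)
    Zh <- Z[, cols, drop = FALSE]
    D <- .addrow(-2 * tcrossprod(Zh, codebook), cb2)  # + rowSums(Zh^2) const
    idx[, h] <- max.col(-D, ties.method = "first")
    Q[, cols] <- codebook[idx[, h], , drop = FALSE]
  }
  list(indices = idx, quantized = Q)
}

#' Quantize latent head vectors against a codebook
#'
#' Each head vector is replaced by the codebook embedding minimizing the
#' Euclidean distance; ties break to the lowest index.  With `H` heads and
#' `K` embeddings the number of distinct representable columns is `K^H`.
#'
#' @param z_heads a matrix with one row per head (or a single vector for
#'   one head), each of the per-head bottleneck dimension.
#' @param codebook `K x q_head` embedding matrix.
#' @return A list with `indices` (1-based, one per head) and `vectors`
#'   (the quantized rows).
#' @seealso [vq_lookup()], [vq_loss()]
#' @export
quantize <- function(z_heads, codebook) {
  if (is.vector(z_heads)) z_heads <- matrix(z_heads, nrow = 1)
  if (is.null(codebook) || nrow(codebook) == 0L) stop("empty codebook")
  if (ncol(z_heads) != ncol(codebook))
    stop("head vectors and codebook embeddings differ in dimension")
  H <- nrow(z_heads)
  flat <- matrix(t(z_heads), nrow = 1)  # heads side by side
  qz <- quantize_batch(flat, codebook, H)
  list(indices = as.integer(qz$indices),
       vectors = matrix(qz$quantized, nrow = H, byrow = TRUE))
}

#' Fetch codebook embeddings for an index matrix
#'
#' @param indices integer matrix (or vector) of 1-based codebook indices,
#'   shaped heads x windows.
#' @param codebook `K x q_head` embedding matrix.
#' @return An array of embeddings: `lookup(quantize(z)$indices)` reproduces
#'   the quantized vectors exactly.
#' @export
vq_lookup <- function(indices, codebook) {
  idx <- as.integer(indices)
  if (any(idx < 1L) || any(idx > nrow(codebook)))
    stop(sprintf("codebook index out of range [1, %d]", nrow(codebook)))
  out <- codebook[idx, , drop = FALSE]
  if (is.matrix(indices))
    dim(out) <- c(dim(indices), ncol(codebook))
  out
}

#' Vector-quantization training objective
#'
#' `total = BCE(x, recon) + ||sg(z) - e||^2 + commit_weight * ||z - sg(e)||^2`
#' where `sg` is the stop-gradient operator (identity in value, blocking
#' updates through its operand).  In value the embedding and commitment
#' terms are both the squared distance between the encoder output and its
#' assigned embedding; they differ only in which side the gradient reaches.
#'
#' @param x binary input vector/matrix.
#' @param recon reconstruction probabilities (or a [decode()] result).
#' @param z encoder outputs (pre-quantization).
#' @param e_k assigned codebook embeddings, same shape as `z`.
#' @param commit_weight weight of the commitment term (default 1).
#' @return A `loss_breakdown` with `bce`, `vq_embed`, `vq_commit`, `total`.
#' @export
vq_loss <- function(x, recon, z, e_k, commit_weight = 1) {
  if (length(z) != length(e_k)) stop("'z' and 'e_k' differ in shape")
  o <- if (inherits(recon, "snp_reconstruction")) recon$prob else recon
  if (length(o) != length(x)) stop("'x' and the reconstruction differ in shape")
  bce <- bce_sum(x, o)
  embed <- sum((z - e_k)^2)
  structure(list(bce = bce, kl = 0, vq_embed = embed, vq_commit = embed,
                 total = bce + embed + commit_weight * embed),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf(
    "loss: total %.5f (bce %.5f, kl %.5f, vq_embed %.5f, vq_commit %.5f)\n",
    x$total, x$bce, x$kl, x$vq_embed, x$vq_commit))
  invisible(x)
}
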