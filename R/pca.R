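#' PCA baseline over a haplotype panel
#'
#' A thin linear baseline with the same surface as [snp_vae()] for the
#' compression and classification comparisons: haplotypes are projected
#' onto the top `k` principal components, and reconstructions are the
#' linear back-projection thresholded at 1/2 — so residual semantics are
#' identical to the VAE's.
#'
#' @param panel a [genotype_panel()] of training haplotypes.
#' @param k number of retained components (the latent dimension).
#' @param standardize standardize the 2-D scores before clustering-metric
#'   use; retained as an attribute, the projection itself is centred only.
#' @return An object of class `snp_pca`.
#' @export
snp_pca <- function(panel, k = 2, standardize = TRUE) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$haplotypes
  storage.mode(X) <- "double"
  k <- min(k, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = k)
  structure(list(d = ncol(X), k = k, rotation = pc$rotation[, seq_len(k),
                                                            drop = FALSE],
                 center = pc$center, sdev = pc$sdev[seq_len(k)],
                 positions = panel$positions, standardize = standardize),
            class = "snp_pca")
}

#' @export
print.snp_pca <- function(x, ...) {
  cat(sprintf("snp_pca: %d-SNP haplotypes -> %d principal components\n",
              x$d, x$k))
  invisible(x)
}

#' Predict method for the PCA baseline
#'
#' @param object an [snp_pca()] fit.
#' @param newdata panel, 0/1 matrix, or single haplotype.
#' @param type `"latent"` (scores), `"prob"` (back-projection clipped to
#'   `[0, 1]`) or `"reconstruction"` (thresholded bits).
#' @param ... unused.
#' @return Per `type`; rows align with `newdata`.
#' @export
predict.snp_pca <- function(object, newdata,
                            type = c("latent", "prob", "reconstruction"),
                            ...) {
  type <- match.arg(type)
  single <- is.vector(newdata) && !inherits(newdata, "genotype_panel")
  X <- as_hap_matrix(newdata, object$d)
  Z <- .addrow(X, -object$center) %*% object$rotation
  if (type == "latent") return(if (single) drop(Z) else Z)
  R <- .addrow(tcrossprod(Z, object$rotation), object$center)
  if (type == "prob") {
    P <- pmin(pmax(R, 0), 1)
    return(if (single) drop(P) else P)
  }
  B <- binarize(R)
  if (single) drop(B) else B
}

#' @export
n_parameters.snp_pca <- function(model) {
  length(model$rotation) + length(model$center)
}

#' @export
model_fingerprint.snp_pca <- function(model) {
  digest::digest(model[c("rotation", "center", "d")], algo = "xxhash64")
}

#' @export
latent_codes.snp_pca <- function(model, x, label = NULL) {
  drop(predict(model, x, type = "latent"))
}

#' @export
reconstruct_from_latent.snp_pca <- function(model, z, label = NULL) {
  R <- .addrow(matrix(z, nrow = 1) %*% t(model$rotation), model$center)
  as.integer(drop(binarize(R)))
}
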