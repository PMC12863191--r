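# Ancestry classification over VAE (or PCA) representations: nearest
# latent centroid, L1 reconstruction discrepancy, and MAP via the Bernoulli
# likelihood / BCE, with log-space clamping for numerical stability.
#
# A "model bank" is anything that yields one Bernoulli probability vector
# per population for an input haplotype: a conditioned snp_vae (C-VAE or
# Y-VAE bank), or — mainly for testing against exact oracles — a named list
# of fixed probability vectors.

LOG_FLOOR <- -100

#' Per-population latent centroids
#'
#' The centroid of population `k` is the mean latent vector of its
#' members.
#'
#' @param latents `N x q` matrix of latent coordinates.
#' @param labels length-`N` population labels.
#' @return A named list of class `centroid_set`, one `q`-vector per label.
#' @export
compute_centroids <- function(latents, labels) {
  latents <- as.matrix(latents)
  if (nrow(latents) != length(labels))
    stop("'latents' and 'labels' differ in length")
  sets <- split(seq_len(nrow(latents)), as.character(labels))
  if (any(lengths(sets) == 0L)) stop("every class needs at least one sample")
  out <- lapply(sets, function(i) colMeans(latents[i, , drop = FALSE]))
  structure(out[order(names(out))], class = "centroid_set")
}

#' Nearest-centroid classification in latent space
#'
#' Assigns the label whose centroid minimizes the Euclidean distance; ties
#' break to the lexicographically smallest label.
#'
#' @param z latent vector, or a matrix with one row per sample.
#' @param centroids a [compute_centroids()] result.
#' @return A `classification_result`: list with `predicted` and `scores`
#'   (per-label distances; lower is better).
#' @export
classify_nearest_centroid <- function(z, centroids) {
  if (length(centroids) == 0L) stop("empty centroid set")
  Z <- if (is.vector(z)) matrix(z, nrow = 1) else as.matrix(z)
  C <- do.call(rbind, centroids)
  if (ncol(Z) != ncol(C)) stop("latent dimension does not match centroids")
  D <- outer(rowSums(Z^2), rep(1, nrow(C))) - 2 * tcrossprod(Z, C) +
    outer(rep(1, nrow(Z)), rowSums(C^2))
  D <- sqrt(pmax(D, 0))
  colnames(D) <- names(centroids)
  pick_best(-D, objective = "nearest_centroid")
}

# argmax over ordered label columns; ties fall to the lexicographically
# smallest label (columns are sorted, max.col "first")
pick_best <- function(score, objective) {
  lab <- colnames(score)[max.col(score, ties.method = "first")]
  ambiguous <- apply(score, 1, function(s) sum(s == max(s)) > 1L)
  structure(list(predicted = lab, scores = score, objective = objective,
                 ambiguous = ambiguous),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("classification (%s): %d sample(s)\n", x$objective,
              length(x$predicted)))
  print(table(predicted = x$predicted))
  invisible(x)
}

# per-label Bernoulli probability matrices for a batch of haplotypes
label_probs <- function(bank, X) {
  if (inherits(bank, "snp_vae")) {
    if (bank$config$conditioning == "none")
      stop("classification needs a conditioned model (cvae or yvae)")
    labs <- sort(bank$labels)
    out <- lapply(labs, function(k)
      predict(bank, X, type = "prob", label = rep(k, nrow(X))))
    names(out) <- labs
    return(out)
  }
  if (is.list(bank)) {
    labs <- sort(names(bank))
    out <- lapply(labs, function(k) {
      o <- bank[[k]]
      if (is.function(o)) o <- t(apply(X, 1, o))
      else if (is.vector(o)) o <- matrix(o, nrow(X), length(o), byrow = TRUE)
      o
    })
    names(out) <- labs
    return(out)
  }
  stop("unsupported model bank")
}

#' Classification by L1 reconstruction discrepancy
#'
#' Each label's conditioned reconstruction is binarized and the label with
#' the smallest L1 distance (Hamming distance, for bits) to the input wins;
#' ties break to the smallest label and are flagged ambiguous.
#'
#' @param x binary haplotype vector, or matrix with one row per sample.
#' @param bank a conditioned [snp_vae()] (C-VAE or Y-VAE), or a named list
#'   mapping labels to probability vectors/functions.
#' @param binarize_recon compare against the thresholded reconstruction
#'   (default; the Hamming distance) or, if `FALSE`, against the raw
#'   Bernoulli probabilities — the quantity whose first-order Taylor
#'   expansion links the L1 objective to the BCE one.
#' @return A `classification_result` with per-label L1 scores.
#' @export
classify_l1 <- function(x, bank, binarize_recon = TRUE) {
  X <- as_hap_matrix(x)
  probs <- label_probs(bank, X)
  L1 <- vapply(probs, function(P)
    rowSums(abs(X - if (binarize_recon) binarize(P) else P)),
    numeric(nrow(X)))
  if (nrow(X) == 1L) L1 <- matrix(L1, nrow = 1,
                                  dimnames = list(NULL, names(probs)))
  pick_best(-L1, objective = "l1")
}

#' MAP classification via the Bernoulli likelihood
#'
#' With a uniform prior over the (balanced) labels, the posterior
#' `p(Y = k | x)` is maximized by minimizing the binary cross-entropy
#' between the input and the label-conditioned Bernoulli probabilities.
#' Per-site probabilities are clipped to `[exp(-100), 1 - exp(-100)]`
#' before the logarithms and the per-label log-score is floored at -100,
#' so scores are always finite.
#'
#' @param x binary haplotype vector, or matrix with one row per sample.
#' @param bank a conditioned [snp_vae()], or a named list of probability
#'   vectors/functions (one per label).
#' @param temperature rescales the decoder's pre-sigmoid activations
#'   (a Laplace-smoothing knob: temperatures above 1 soften the
#'   probabilities); default 1.
#' @param prior optional named prior weights over labels (default
#'   uniform).
#' @return A `classification_result` with per-label clamped log-posterior
#'   scores (higher is better).
#' @export
classify_map <- function(x, bank, temperature = 1, prior = NULL) {
  X <- as_hap_matrix(x)
  probs <- label_probs(bank, X)
  score <- vapply(probs, function(P) {
    if (anyNA(P)) stop("NaN in model probabilities")
    if (temperature != 1) P <- sigmoid(qlogis(pmin(pmax(P, 1e-12),
                                                   1 - 1e-12)) / temperature)
    lo <- pmax(log(P), LOG_FLOOR)
    l1o <- pmax(log1p(-P), LOG_FLOOR)
    s <- rowSums(X * lo + (1 - X) * l1o)
    pmax(s, LOG_FLOOR)
  }, numeric(nrow(X)))
  if (nrow(X) == 1L) score <- matrix(score, nrow = 1,
                                     dimnames = list(NULL, names(probs)))
  if (!is.null(prior)) {
    lp <- log(prior[colnames(score)] / sum(prior))
    score <- .addrow(score, lp)
  }
  pick_best(score, objective = "map")
}

#' Overall and per-label classification accuracy
#'
#' @param predictions predicted labels (or a `classification_result`).
#' @param truth true labels of the same length.
#' @return A data frame with one row per label plus an `"overall"` row;
#'   accuracies in percent.
#' @export
evaluate_accuracy <- function(predictions, truth) {
  if (inherits(predictions, "classification_result"))
    predictions <- predictions$predicted
  if (length(predictions) != length(truth))
    stop("'predictions' and 'truth' differ in length")
  truth <- as.character(truth)
  labs <- sort(unique(truth))
  rows <- lapply(labs, function(k) {
    i <- truth == k
    data.frame(label = k, n = sum(i),
               accuracy = 100 * mean(predictions[i] == truth[i]))
  })
  rbind(do.call(rbind, rows),
        data.frame(label = "overall", n = length(truth),
                   accuracy = 100 * mean(predictions == truth)))
}

#' End-to-end latent-centroid classifier
#'
#' Convenience wrapper: encode a training panel, compute centroids, then
#' classify query haplotypes by nearest centroid.  Works with both
#' [snp_vae()] and [snp_pca()] representations.
#'
#' @param model a fitted [snp_vae()] or [snp_pca()].
#' @param train_panel labelled panel used for the centroids.
#' @param query panel/matrix to classify.
#' @return A `classification_result`.
#' @export
classify_centroid_model <- function(model, train_panel, query) {
  Ztr <- if (inherits(model, "snp_pca"))
    predict(model, train_panel, type = "latent")
  else encode(model, train_panel)$mu
  cen <- compute_centroids(Ztr, train_panel$populations)
  Zq <- if (inherits(model, "snp_pca")) predict(model, query, type = "latent")
  else encode(model, query)$mu
  classify_nearest_centroid(Zq, cen)
}
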