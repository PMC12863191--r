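# Conditional genotype simulation from trained models: standard-normal
# prior sampling through a conditioned decoder, and the centroid-Gaussian
# baseline for unconditional VAEs.

#' Simulate ancestry-specific haplotypes from a conditioned model
#'
#' Draws `z ~ N(0, I)` in the `q`-dimensional latent space and maps it
#' through the decoder conditioned on population `label` (one-hot input for
#' a C-VAE, the population's own decoder for a Y-VAE bank).  Outputs are
#' thresholded at 1/2 by default; `output_mode = "bernoulli"` instead
#' samples each site from its decoded probability, preserving
#' within-population diversity at the cost of marginal noise.
#'
#' @param model a fitted conditioned [snp_vae()] (`"cvae"` or `"yvae"`).
#' @param label population label to condition on.
#' @param n_samples number of haplotypes to generate (>= 0).
#' @param seed integer seed; identical seeds give identical panels.
#' @param output_mode `"threshold"` or `"bernoulli"`.
#' @return A [genotype_panel()] of `n_samples` haplotypes labelled `label`.
#' @export
sample_conditional <- function(model, label, n_samples, seed = 1L,
                               output_mode = c("threshold", "bernoulli")) {
  stopifnot(inherits(model, "snp_vae"), n_samples >= 0)
  output_mode <- match.arg(output_mode)
  if (model$config$conditioning == "none")
    stop(paste("model is unconditional: use sample_centroid_gaussian()",
               "for the centroid-Gaussian path"))
  q <- total_latent_dim(model)
  local_rng(seed)
  if (n_samples == 0L)
    return(genotype_panel(matrix(0L, 0, model$d), model$positions,
                          character(0), character(0)))
  Z <- matrix(rnorm(n_samples * q), n_samples, q)
  rec <- decode(model, Z, rep(label, n_samples))
  bits <- finalize_bits(rec$prob, output_mode)
  genotype_panel(bits, model$positions,
                 sprintf("%s_sim%04d", label, seq_len(n_samples)),
                 rep(label, n_samples))
}

#' Centroid-Gaussian sampling from an unconditional VAE
#'
#' Estimates the population's latent mean and per-dimension variance from
#' a labelled reference panel, samples `z ~ N(mu, sigma^2 I)` and decodes
#' with the unconditional decoder.  This is the baseline conditioning-free
#' simulation path; with a single reference haplotype (or `sigma^2`
#' forced to 0) every sample is the decoded centroid.
#'
#' @param model a fitted unconditional [snp_vae()].
#' @param reference_panel labelled [genotype_panel()] supplying the
#'   latents.
#' @param label which population's centroid to sample around.
#' @param n_samples number of haplotypes to generate.
#' @param seed integer seed.
#' @param output_mode `"threshold"` or `"bernoulli"`.
#' @param sigma_scale multiplier on the estimated latent standard
#'   deviation (0 collapses all samples onto the centroid).
#' @return A [genotype_panel()] labelled `label`.
#' @export
sample_centroid_gaussian <- function(model, reference_panel, label,
                                     n_samples, seed = 1L,
                                     output_mode = c("threshold", "bernoulli"),
                                     sigma_scale = 1) {
  stopifnot(inherits(model, "snp_vae"), n_samples >= 0)
  output_mode <- match.arg(output_mode)
  sel <- reference_panel$populations == label
  if (!any(sel))
    stop(sprintf("label '%s' absent from the reference panel", label))
  Zref <- encode(model, reference_panel[which(sel)])$mu
  mu <- colMeans(Zref)
  sdv <- if (nrow(Zref) > 1L) apply(Zref, 2, stats::sd) else rep(0, length(mu))
  sdv <- sdv * sigma_scale
  q <- length(mu)
  local_rng(seed)
  if (n_samples == 0L)
    return(genotype_panel(matrix(0L, 0, model$d), model$positions,
                          character(0), character(0)))
  Z <- .addrow(.mulrow(matrix(rnorm(n_samples * q), n_samples, q), sdv), mu)
  rec <- decode(model, Z)
  bits <- finalize_bits(rec$prob, output_mode)
  genotype_panel(bits, model$positions,
                 sprintf("%s_cg%04d", label, seq_len(n_samples)),
                 rep(label, n_samples))
}

finalize_bits <- function(P, output_mode) {
  if (is.vector(P)) P <- matrix(P, nrow = 1)
  if (output_mode == "bernoulli") {
    B <- matrix(rbinom(length(P), 1L, as.vector(P)), nrow(P))
  } else {
    B <- binarize(P)
  }
  storage.mode(B) <- "integer"
  B
}

#' Simulate method for SNP VAEs
#'
#' Dispatches to [sample_conditional()] for conditioned models and to
#' [sample_centroid_gaussian()] (which then requires `reference_panel`)
#' for unconditional ones.
#'
#' @param object a fitted [snp_vae()].
#' @param nsim number of haplotypes.
#' @param seed integer seed.
#' @param label population label.
#' @param reference_panel labelled panel (unconditional models only).
#' @param output_mode `"threshold"` or `"bernoulli"`.
#' @param ... unused.
#' @return A [genotype_panel()].
#' @export
simulate.snp_vae <- function(object, nsim = 1, seed = 1L, label = NULL,
                             reference_panel = NULL,
                             output_mode = "threshold", ...) {
  if (object$config$conditioning == "none") {
    if (is.null(reference_panel) || is.null(label))
      stop("unconditional models need 'reference_panel' and 'label'")
    sample_centroid_gaussian(object, reference_panel, label, nsim, seed,
                             output_mode)
  } else {
    if (is.null(label)) stop("conditioned models need 'label'")
    sample_conditional(object, label, nsim, seed, output_mode)
  }
}
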