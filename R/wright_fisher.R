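#' Draw founder haplotypes with population-specific allele frequencies
#'
#' Generation-0 pools for the forward simulator.  Column `i` of population
#' `k` is sampled i.i.d. Bernoulli with the frequency supplied for that
#' population and site, so populations can be given differentiated allele
#' frequencies (and hence per-SNP entropies).
#'
#' @param n_per_population haplotypes per population (integer >= 1).
#' @param n_snps number of SNP columns (integer >= 1).
#' @param freq allele-frequency model.  One of: a single number (shared by
#'   all populations and sites), a numeric vector of length `n_snps` (one
#'   population), a matrix with one row per population, or a function
#'   `f(population, n_snps)` returning a frequency vector.
#' @param populations character vector of population names.
#' @param seed integer seed.
#' @param positions optional variant positions (default `1:n_snps`).
#' @return A [genotype_panel()] holding all founder pools, labelled by
#'   population.
#' @export
generate_founders <- function(n_per_population, n_snps, freq,
                              populations = "pop1", seed = 1L,
                              positions = NULL) {
  stopifnot(n_per_population >= 1L, n_snps >= 1L)
  populations <- as.character(populations)
  freq_for <- function(pop) {
    p <- if (is.function(freq)) freq(pop, n_snps)
    else if (is.matrix(freq)) freq[match(pop, populations), ]
    else freq
    if (length(p) == 1L) p <- rep(p, n_snps)
    if (length(p) != n_snps || anyNA(p) || any(!is.finite(p)) ||
        any(p < 0 | p > 1))
      stop("allele frequencies must be finite values in [0, 1]")
    p
  }
  local_rng(seed)
  mats <- lapply(populations, function(pop) {
    p <- freq_for(pop)
    matrix(rbinom(n_per_population * n_snps, 1L, rep(p, each = n_per_population)),
           nrow = n_per_population, ncol = n_snps)
  })
  hap <- do.call(rbind, mats)
  n_tot <- nrow(hap)
  genotype_panel(
    hap,
    positions = if (is.null(positions)) seq_len(n_snps) else positions,
    sample_ids = sprintf("%s_f%03d", rep(populations, each = n_per_population),
                         sequence(rep(n_per_population, length(populations)))),
    populations = rep(populations, each = n_per_population))
}

#' Wright-Fisher forward simulation of haplotype panels
#'
#' Evolves each population forward in discrete generations: every haplotype
#' of a new generation picks two parents uniformly with replacement from the
#' previous generation of its own population, recombines them with a
#' Poisson-distributed crossover count at uniformly chosen breakpoints
#' between adjacent SNP indices, and (optionally) applies per-site mutation
#' flips.  Limited recombination over many generations induces the blockwise
#' linkage disequilibrium that the downstream models exploit.
#'
#' @param founders a [genotype_panel()] of generation-0 haplotypes (e.g. from
#'   [generate_founders()]); each population evolves independently.
#' @param n_generations number of generations to simulate (>= 0; 0 returns
#'   the founders unchanged).
#' @param generation_size haplotypes per population per generation (>= 1).
#' @param recombination_rate expected crossovers per haplotype per meiosis.
#' @param mutation_rate per-site flip probability (default 0).
#' @param seed integer seed; identical seeds give bit-identical panels.
#' @return A [genotype_panel()] holding the final generation, with inherited
#'   positions and population labels.
#' @export
simulate_wright_fisher <- function(founders, n_generations, generation_size,
                                   recombination_rate = 0.5,
                                   mutation_rate = 0, seed = 1L) {
  stopifnot(inherits(founders, "genotype_panel"))
  if (nrow(founders$haplotypes) == 0L) stop("'founders' is empty")
  if (n_generations < 0L) stop("'n_generations' must be >= 0")
  if (generation_size < 1L) stop("'generation_size' must be >= 1")
  if (recombination_rate < 0 || mutation_rate < 0)
    stop("rates must be >= 0")
  if (n_generations == 0L) return(founders)
  pops <- unique(founders$populations)
  d <- ncol(founders$haplotypes)
  local_rng(seed)
  out <- lapply(pops, function(pop) {
    H <- founders$haplotypes[founders$populations == pop, , drop = FALSE]
    if (nrow(H) == 0L) stop(sprintf("population '%s' has no founders", pop))
    for (g in seq_len(n_generations)) {
      H <- wf_next_generation(H, generation_size, recombination_rate,
                              mutation_rate)
    }
    H
  })
  hap <- do.call(rbind, out)
  genotype_panel(
    hap, positions = founders$positions,
    sample_ids = sprintf("%s_g%d_i%04d", rep(pops, each = generation_size),
                         n_generations,
                         sequence(rep(generation_size, length(pops)))),
    populations = rep(pops, each = generation_size))
}

# One generation: generation_size children, each a crossover mosaic of two
# uniformly chosen parent haplotypes.
wf_next_generation <- function(H, generation_size, recombination_rate,
                               mutation_rate) {
  n <- nrow(H); d <- ncol(H)
  child <- matrix(0L, generation_size, d)
  p1 <- sample.int(n, generation_size, replace = TRUE)
  p2 <- sample.int(n, generation_size, replace = TRUE)
  n_cross <- if (recombination_rate > 0)
    rpois(generation_size, recombination_rate) else integer(generation_size)
  for (i in seq_len(generation_size)) {
    a <- H[p1[i], ]; b <- H[p2[i], ]
    k <- min(n_cross[i], d - 1L)
    if (k > 0L) {
      # breakpoints between SNP indices: segment starts alternate parents
      cuts <- sort(sample.int(d - 1L, k))
      seg_len <- diff(c(0L, cuts, d))
      from_a <- rep(c(TRUE, FALSE), length.out = k + 1L)
      if (sample.int(2L, 1L) == 2L) from_a <- !from_a
      mask <- rep(from_a, seg_len)
      child[i, ] <- ifelse(mask, a, b)
    } else {
      child[i, ] <- if (sample.int(2L, 1L) == 1L) a else b
    }
  }
  if (mutation_rate > 0) {
    n_mut <- rbinom(1L, generation_size * d, mutation_rate)
    if (n_mut > 0L) {
      idx <- sample.int(generation_size * d, n_mut)
      child[idx] <- 1L - child[idx]
    }
  }
  child
}
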