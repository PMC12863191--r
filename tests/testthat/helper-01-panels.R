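# Shared fixtures, built in code once per test run.

# i.i.d. Bernoulli panel (no LD)
iid_panel <- function(n, d, p = 0.5, seed = 1, populations = "pop1") {
  withr::with_seed(seed, {
    hap <- matrix(rbinom(n * d, 1L, p), n, d)
  })
  genotype_panel(hap, populations = rep(populations, length.out = n))
}

# two well-separated populations: founder allele frequencies 0.1 vs 0.9,
# drifted and recombined into LD structure
two_pop_panel <- function(n_per_pop = 120, d = 200, seed = 11,
                          generations = 20) {
  founders <- generate_founders(
    60, d, freq = matrix(c(rep(0.1, d), rep(0.9, d)), 2, byrow = TRUE),
    populations = c("POP_A", "POP_B"), seed = seed)
  simulate_wright_fisher(founders, generations, n_per_pop,
                         recombination_rate = 0.3, seed = seed + 1)
}

# single low-diversity population with blockwise LD
drifted_panel <- function(n = 200, d = 300, seed = 21) {
  founders <- generate_founders(
    40, d, freq = function(pop, dd) stats::rbeta(dd, 0.8, 0.8),
    populations = "pop1", seed = seed)
  simulate_wright_fisher(founders, 60, n, recombination_rate = 0.2,
                         seed = seed + 1)
}
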