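Package: genolatent
Title: Variational Autoencoders for Lossless Compression, Classification
    and Simulation of SNP Haplotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Window-based variational autoencoders (VAEs) for binary phased
    SNP haplotype panels, with ancestry conditioning (one-hot conditional
    VAE and per-population model banks), an optional vector-quantized
    discrete bottleneck with multihead codebooks, lossless compression via
    latent plus run-length-encoded residual coding, Bayesian-motivated
    ancestry classification (nearest latent centroid, L1 discrepancy, and
    MAP via Bernoulli likelihood), conditional genotype simulation, and an
    evaluation suite covering SNP entropy, mutual information, linkage
    disequilibrium profiles, folded allele-frequency spectra and clustering
    quality.  A built-in Wright-Fisher forward simulator provides
    multi-population synthetic panels with realistic linkage disequilibrium
    for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    cluster,
    digest,
    jsonlite,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
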