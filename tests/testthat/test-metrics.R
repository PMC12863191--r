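test_that("SNP entropy matches its closed form and symmetry", {
  p <- genotype_panel(rbind(c(0, 1, 0, 1), c(0, 1, 0, 0),
                            c(0, 1, 1, 0), c(0, 1, 1, 0)))
  h <- snp_entropy(p)
  expect_equal(h[1], 0)                  # monomorphic 0
  expect_equal(h[2], 0)                  # monomorphic 1
  expect_equal(h[3], 1)                  # p = 0.5
  expect_equal(h[4], 0.811278, tolerance = 1e-6)  # p = 0.25
  expect_equal(genolatent:::binary_entropy(0.25),
               genolatent:::binary_entropy(0.75))
  expect_true(all(h >= 0 & h <= 1))
  expect_error(snp_entropy(genotype_panel(matrix(0L, 0, 3))), "empty")
})

test_that("bootstrap entropy is unbiased on degenerate and fixed panels", {
  same <- genotype_panel(matrix(rep(c(0L, 1L, 1L, 0L), each = 10), 10),
                         populations = rep("P", 10))
  rep0 <- bootstrap_population_entropy(same, m = 5, reps = 10, seed = 1)
  expect_equal(unname(rep0$per_population_mean), 0)

  # convergence to the plug-in estimate; m is kept large enough that the
  # Jensen bias of the m-sample entropy estimate, about 1/(2 m ln 2) bits,
  # sits inside the tolerance band
  p <- iid_panel(400, 40, p = 0.3, seed = 111)
  plug_in <- mean(snp_entropy(p))
  boot <- bootstrap_population_entropy(p, m = 64, reps = 500, seed = 2)
  expect_lt(abs(unname(boot$per_population_mean) - plug_in), 0.02)

  expect_identical(bootstrap_population_entropy(p, seed = 3),
                   bootstrap_population_entropy(p, seed = 3))
  expect_error(bootstrap_population_entropy(p, m = 0), ">= 1")
})

test_that("mutual information matches the contingency-table oracle", {
  x <- rep(c(0, 1), 50)
  expect_equal(mutual_information(x, x), 1)  # I(X;X) = H(X) at p = 0.5
  expect_equal(mutual_information(x, rep(0, 100)), 0)

  # joint counts {00:40, 01:10, 10:10, 11:40}
  a <- rep(c(0, 0, 1, 1), c(40, 10, 10, 40))
  b <- rep(c(0, 1, 0, 1), c(40, 10, 10, 40))
  oracle <- 2 * 0.4 * log2(0.4 / 0.25) + 2 * 0.1 * log2(0.1 / 0.25)
  expect_equal(mutual_information(a, b), oracle, tolerance = 1e-12)
  expect_equal(mutual_information(a, b), mutual_information(b, a))
  expect_lte(mutual_information(a, b),
             min(genolatent:::binary_entropy(mean(a)),
                 genolatent:::binary_entropy(mean(b))) + 1e-12)
  expect_error(mutual_information(a, b[1:10]), "length")
})

test_that("the stride map anchors at H(ref) and stays symmetric", {
  p <- iid_panel(2000, 30, seed = 112)
  m <- mi_stride_map(p, 5, strides = c(0, 1, 2), offsets = c(1, 3, 5))
  h_ref <- snp_entropy(p)[5]
  expect_equal(unname(m[1, ]), rep(h_ref, 3))
  # iid columns carry negligible information at N = 2000
  expect_true(all(m[-1, ] < 0.05))
  expect_error(mi_stride_map(p, 5, strides = 10, offsets = 10),
               "out of range")
})

test_that("LD profiles separate linked from independent panels", {
  iid <- iid_panel(2000, 60, seed = 113)
  prof <- ld_profile(iid, n_refs = 20, max_distance = 20, seed = 1)
  expect_true(all(prof$mean_correlation < 3 / sqrt(2000)))

  wf <- drifted_panel(n = 300, d = 200, seed = 114)
  lp <- ld_profile(wf, n_refs = 30, max_distance = 100, seed = 2)
  ok <- is.finite(lp$mean_correlation)
  trend <- cor(lp$distance[ok], lp$mean_correlation[ok], method = "spearman")
  expect_lt(trend, 0)

  # zero-variance columns are excluded, not NA
  m <- iid$haplotypes
  m[, 2] <- 0L
  lp2 <- ld_profile(genotype_panel(m), n_refs = 60, max_distance = 5,
                    seed = 3)
  expect_gt(lp2$n_excluded, 0)

  expect_error(ld_profile(iid, max_distance = 60), "smaller than d")
})

test_that("folded spectra bin by minor-allele frequency", {
  half <- genotype_panel(matrix(rep(c(0L, 1L), each = 5), 10, 4))
  a <- folded_afs(half)
  expect_equal(a$count[50], 4)
  expect_equal(sum(a$count) + a$monomorphic, 4)

  mono <- genotype_panel(matrix(1L, 6, 5))
  b <- folded_afs(mono)
  expect_equal(b$monomorphic, 5)
  expect_true(all(b$count == 0))

  # hand-built frequencies over 10 haplotypes: p = .1, .2, .5, .9, 1
  hap <- sapply(c(1, 2, 5, 9, 10), function(k) rep(c(1L, 0L), c(k, 10 - k)))
  h <- folded_afs(genotype_panel(hap))
  expect_equal(h$count[10], 2)  # p = .1 and p = .9 both fold to 10%
  expect_equal(h$count[20], 1)
  expect_equal(h$count[50], 1)
  expect_equal(h$monomorphic, 1)
  # invariance under global allele relabelling
  flipped <- folded_afs(genotype_panel(1L - hap))
  expect_identical(h$count, flipped$count)
})

test_that("window selection maximizes the gap product", {
  # all-identical haplotypes: zero entropy everywhere, smallest candidate
  same <- genotype_panel(matrix(rep(c(0L, 1L), 50), 8, 100, byrow = TRUE))
  e0 <- intrawindow_entropy(same, c(10, 20, 50))
  expect_true(all(e0 == 0))
  expect_equal(select_window_size(c(10, 20, 50), e0), 10)

  # constructed entropy list: the elbow interval's right endpoint wins
  w <- c(50, 100, 500, 1000, 2500)
  E <- c(0.1, 0.2, 0.3, 0.31, 0.32)
  expect_equal(select_window_size(w, E), 500)

  # brute-force oracle over random candidate lists
  withr::with_seed(115, {
    for (i in 1:50) {
      ww <- sort(sample(10:10000, 6))
      ee <- cumsum(runif(6, 0, 0.3))
      gain <- diff(ww) * diff(ee)
      expect_equal(select_window_size(ww, ee), ww[which.max(gain) + 1])
    }
  })

  # the production candidate grid runs end to end
  big <- iid_panel(40, 10000, seed = 116)
  eb <- intrawindow_entropy(big)
  expect_length(eb, 8)
  expect_true(all(eb <= log2(40) + 1e-12))
  expect_true(select_window_size(c(50, 100, 500, 1000, 2500, 5000, 7500,
                                   10000), eb) %in%
                c(50, 100, 500, 1000, 2500, 5000, 7500, 10000))

  expect_error(intrawindow_entropy(same, c(10, 2000)), "exceeds")
  expect_error(select_window_size(c(10, 5), c(1, 2)), "ascending")
})

test_that("cluster scores match textbook formula reimplementations", {
  # two tight, far-separated clusters
  withr::with_seed(117, {
    Z <- rbind(matrix(rnorm(40, 0, 0.05), 20),
               matrix(rnorm(40, 8, 0.05), 20))
    labs <- rep(c("a", "b"), each = 20)
  })
  cs <- cluster_scores(Z, labs)
  expect_gt(cs$silhouette, 0.9)
  expect_lt(cs$dbi, 0.1)

  withr::with_seed(118, shuffled <- sample(labs))
  expect_lt(abs(cluster_scores(Z, shuffled)$silhouette), 0.1)

  # 10-point toy set against brute-force formulas
  withr::with_seed(119, {
    Z10 <- matrix(rnorm(20), 10, 2)
    l10 <- rep(c("u", "v"), each = 5)
  })
  cs10 <- cluster_scores(Z10, l10)
  S <- scale(Z10)
  cen <- rbind(colMeans(S[1:5, ]), colMeans(S[6:10, ]))
  # Calinski-Harabasz
  wss <- sum((S[1:5, ] - rep(cen[1, ], each = 5))^2) +
    sum((S[6:10, ] - rep(cen[2, ], each = 5))^2)
  bss <- 5 * sum((cen[1, ] - colMeans(S))^2) +
    5 * sum((cen[2, ] - colMeans(S))^2)
  expect_equal(cs10$pseudo_f, (bss / 1) / (wss / 8), tolerance = 1e-10)
  # Davies-Bouldin
  s1 <- mean(sqrt(rowSums((S[1:5, ] - rep(cen[1, ], each = 5))^2)))
  s2 <- mean(sqrt(rowSums((S[6:10, ] - rep(cen[2, ], each = 5))^2)))
  expect_equal(cs10$dbi, (s1 + s2) / sqrt(sum((cen[1, ] - cen[2, ])^2)),
               tolerance = 1e-10)
  # silhouette
  sil <- vapply(1:10, function(i) {
    own <- setdiff(which(l10 == l10[i]), i)
    oth <- which(l10 != l10[i])
    a <- mean(sqrt(colSums((t(S[own, ]) - S[i, ])^2)))
    b <- mean(sqrt(colSums((t(S[oth, ]) - S[i, ])^2)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(cs10$silhouette, mean(sil), tolerance = 1e-10)

  expect_error(cluster_scores(Z10, c(rep("u", 9), "v")), "singleton.*v")
})

test_that("a founder bottleneck reduces downstream mean entropy", {
  founders <- generate_founders(50, 80, freq = 0.5, seed = 120)
  full <- simulate_wright_fisher(founders, 10, 100,
                                 recombination_rate = 0.3, seed = 121)
  squeezed <- simulate_wright_fisher(founders[1:5], 10, 100,
                                     recombination_rate = 0.3, seed = 121)
  expect_lt(mean(snp_entropy(squeezed)), mean(snp_entropy(full)))
})
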