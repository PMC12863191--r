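test_that("quantization returns the exact nearest codebook row", {
  withr::with_seed(61, {
    cb <- matrix(runif(16 * 4, -1, 1), 16, 4)
    # exact match maps to its own row
    q <- quantize(cb[3, ], cb)
    expect_identical(q$indices, 3L)
    expect_identical(as.vector(q$vectors), cb[3, ])
    # brute-force nearest-neighbour oracle, K up to 64 and q_head up to 8
    for (K in c(4, 16, 64)) for (qh in c(2, 8)) {
      cbk <- matrix(runif(K * qh, -1, 1), K, qh)
      for (i in 1:20) {
        z <- runif(qh, -1.5, 1.5)
        oracle <- which.min(colSums((t(cbk) - z)^2))
        expect_identical(quantize(z, cbk)$indices, as.integer(oracle))
      }
    }
  })
})

test_that("ties break to the lowest codebook index", {
  cb <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_identical(quantize(c(1, 0), cb)$indices, 1L)
  expect_error(quantize(c(1, 0), cb[integer(0), , drop = FALSE]), "empty")
})

test_that("lookup inverts quantization and validates indices", {
  withr::with_seed(62, {
    cb <- matrix(runif(8 * 3, -1, 1), 8, 3)
    z <- matrix(runif(4 * 3), 4, 3)  # 4 heads
    q <- quantize(z, cb)
    expect_identical(vq_lookup(q$indices, cb),
                     q$vectors[seq_along(q$indices), , drop = FALSE])
    expect_identical(vq_lookup(rep(1L, 5), cb)[1, ], cb[1, ])
    expect_error(vq_lookup(9L, cb), "out of range")
  })
})

test_that("the index matrix has shape heads x windows with valid entries", {
  p <- drifted_panel(n = 40, d = 10, seed = 63)
  m <- snp_vae(p, window_size = 4, bottleneck = 2, heads = 2,
               hidden = c(8, 6, 4), use_vq = TRUE, codebook_size = 4,
               epochs = 2, batch_size = 16, seed = 64)
  enc <- genolatent:::vq_indices(m, p$haplotypes[1, ])
  expect_identical(dim(enc$indices), c(2L, 3L))  # H x ceiling(d/w)
  expect_true(all(enc$indices >= 1 & enc$indices <= 4))
})

test_that("the VQ objective matches direct arithmetic", {
  perfect <- vq_loss(c(1, 0), c(1, 0), z = c(0.5, 0.5), e_k = c(0.5, 0.5))
  expect_equal(perfect$total, 0)
  l <- vq_loss(c(1), c(1), z = c(1, 0), e_k = c(0, 0), commit_weight = 1)
  expect_equal(l$vq_embed, 1)
  expect_equal(l$total, 2)  # 0 BCE + 1 embedding + 1 commitment
  expect_error(vq_loss(c(1), c(1), z = c(1, 0), e_k = c(0)), "shape")
})

test_that("straight-through + commitment gradients match finite differences", {
  # deterministic VQ forward: the analytic encoder-weight gradient must
  # equal the numeric derivative of
  #   bce(decoder(e0 + z(W) - z0)) + commit * ||z(W) - e0||^2
  # with the assignment e0 frozen (the stop-gradient contract)
  p <- iid_panel(2, 6, seed = 65)
  m <- snp_vae(p, bottleneck = 2, hidden = c(5, 4, 3), use_vq = TRUE,
               codebook_size = 4, dropout = 0, epochs = 0, seed = 66)
  cfg <- m$config
  Xw <- p$haplotypes
  storage.mode(Xw) <- "double"

  st <- genolatent:::train_step_window(m$nets[[1]], m$codebook, Xw, NULL, cfg)
  # forward pass replicating train_step_window with a frozen assignment
  frozen <- NULL
  loss_at <- function(net) {
    f1 <- genolatent:::dense_forward(net$enc$l1, Xw, TRUE, 0)
    f2 <- genolatent:::dense_forward(net$enc$l2, f1$out, TRUE, 0)
    f3 <- genolatent:::dense_forward(net$enc$l3, f2$out, TRUE, 0)
    fz <- genolatent:::dense_forward(net$enc$z, f3$out, activation = "none")
    Z <- tanh(fz$out)
    if (is.null(frozen)) frozen <<- list(
      Q = genolatent:::quantize_batch(Z, m$codebook, cfg$heads)$quantized,
      Z0 = Z)
    Vd <- frozen$Q + (Z - frozen$Z0)      # straight-through surrogate
    g1 <- genolatent:::dense_forward(net$dec$l1, Vd, TRUE, 0)
    g2 <- genolatent:::dense_forward(net$dec$l2, g1$out, TRUE, 0)
    g3 <- genolatent:::dense_forward(net$dec$l3, g2$out, TRUE, 0)
    O <- genolatent:::dense_forward(net$dec$out, g3$out,
                                    activation = "none")$out
    bce <- sum(pmax(O, 0) - O * Xw + log1p(exp(-abs(O)))) / nrow(Xw)
    commit <- cfg$commit_weight * sum((Z - frozen$Q)^2) / nrow(Xw)
    bce + commit
  }
  h <- 1e-5
  for (probe in list(c(1, 1), c(3, 2), c(6, 5))) {
    net_p <- m$nets[[1]]
    net_p$enc$l1$W[probe[1], probe[2]] <-
      net_p$enc$l1$W[probe[1], probe[2]] + h
    net_m <- m$nets[[1]]
    net_m$enc$l1$W[probe[1], probe[2]] <-
      net_m$enc$l1$W[probe[1], probe[2]] - h
    fd <- (loss_at(net_p) - loss_at(net_m)) / (2 * h)
    expect_equal(st$grads$enc$l1$W[probe[1], probe[2]], fd,
                 tolerance = 1e-4)
  }
})

test_that("VQ training reduces reconstruction loss and uses several codes", {
  # two-cluster toy data: gradients must flow despite the hard quantizer
  withr::with_seed(67, {
    template <- rbind(rep(c(0L, 1L), each = 20), rep(c(1L, 0L), each = 20))
    hap <- template[rep(1:2, 30), ]
    flip <- matrix(rbinom(length(hap), 1, 0.02), nrow(hap))
    hap <- abs(hap - flip)
  })
  p <- genotype_panel(hap)
  used_multiple <- logical(5)
  improved <- logical(5)
  for (s in 1:5) {
    m <- snp_vae(p, bottleneck = 4, hidden = c(32, 16, 8), use_vq = TRUE,
                 codebook_size = 8, dropout = 0, epochs = 15,
                 batch_size = 20, seed = 70 + s)
    h <- m$loss_history
    improved[s] <- h$bce[nrow(h)] < h$bce[1]
    idx <- genolatent:::quantize_batch(encode(m, p)$mu, m$codebook,
                                       genolatent:::total_heads(m))$indices
    used_multiple[s] <- length(unique(as.vector(idx))) > 1
  }
  expect_gte(sum(improved), 3)
  expect_gte(sum(used_multiple), 3)
})
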