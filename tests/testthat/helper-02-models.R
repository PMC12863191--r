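# Small trained models shared across test files (built once per run).
# Training is kept deliberately tiny; properties tested against them are
# qualitative (separable populations, decreasing loss), not calibrated.

tp_panel <- two_pop_panel()
tp_split <- split_panel(tp_panel, c(0.75, 0.25), stratify = TRUE, seed = 12)

small_cfg <- list(bottleneck = 4, hidden = c(64, 32, 16), dropout = 0,
                  epochs = 40, batch_size = 32, learning_rate = 1e-3)

tp_cvae <- do.call(snp_vae, c(list(panel = tp_split$train,
                                   conditioning = "cvae", seed = 31),
                              small_cfg))
tp_yvae <- do.call(snp_vae, c(list(panel = tp_split$train,
                                   conditioning = "yvae", seed = 32),
                              small_cfg))
tp_vae <- do.call(snp_vae, c(list(panel = tp_split$train, seed = 33),
                             small_cfg))
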