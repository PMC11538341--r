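# The trained reference localizer is expensive to build, and two
# acceptance checks (locus accuracy on structured background, bead
# precision on uniform background) evaluate the same training; train it
# once per test run on first use.

acceptance_model <- function() {
  if (is.null(fx$model)) {
    cfg <- locnet_config(tile = 16, base = 8, depth = 2, n_stages = 2,
                         batch_size = 4, iterations = 22000, seed = 1)
    fx$model <- train_reference_model(cfg)
  }
  fx$model
}
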