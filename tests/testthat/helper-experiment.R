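# The scaled-down training-vs-baseline experiment is the most expensive
# computation in the suite; it is run once and shared by every test that
# needs a trained model.
.expCache <- new.env(parent = emptyenv())

cachedExperiment <- function() {
  if (is.null(.expCache$ex))
    .expCache$ex <- runDemosaicExperiment(seed = 1L)
  .expCache$ex
}
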