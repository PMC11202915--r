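# Shared fixtures, generated in code.

# deterministic band-limited test signal reproducible across languages
toySignal <- function(n = 32L) {
  i <- seq_len(n)
  sin(i / 3) + 0.1 * cos(i)
}

# small, fast simulation configuration for imaging tests
smallConfig <- function(...) {
  simConfig(cube_shape = c(24L, 24L), n_bands = 64L, ...)
}

# a trained level-4 db5 model on the default cohort, cached per test run
cachedModel <- local({
  model <- NULL
  function() {
    if (is.null(model)) {
      coh <- simulateCohort(seed = 11L)
      labs <- droplevels(stageLabels(coh))
      feats <- featureMatrix(coh, "db5", 4L)
      model <<- trainStageSVM(feats, labs, list(C = 10, sigma = 3),
                              wavelet = "db5", level = 4L,
                              wavelengths = wavelengths(coh))
    }
    model
  }
})

# coefficient length after k cascade steps
coeffLengthAt <- function(n, wavelet, k) {
  for (j in seq_len(k)) n <- coeffLength(n, wavelet)
  n
}
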