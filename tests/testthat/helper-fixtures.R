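# Shared small fixtures, built in code with fixed seeds.

# A small trained model + phantom pair, computed once per test run.
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- generate_phantom(phantom_spec(shape = c(32, 96, 96), n_cells = 12,
                                          clustering = 0.5, snr = 5, seed = 11))
      anns <- phantom_annotations(ph, n_planes = 4)
      model <- train_proximity(ph$volume, anns, sigma = 4, seed = 0)
      cache <<- list(phantom = ph, annotations = anns, model = model)
    }
    cache
  }
})

# Tiny two-blob proximity-like volume with known centres.
two_blob_volume <- function(sep = 14, sigma = 2.5, dims = c(17, 31, 31)) {
  c1 <- c(8, 15, 8)
  c2 <- c(8, 15, 8 + sep)
  v <- pmax(gaussian_blob(dims, c1, sigma), gaussian_blob(dims, c2, sigma))
  arr <- array(0, c(1, dims))
  arr[1, , , ] <- v
  list(volume = arr, centres = rbind(c1, c2))
}
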