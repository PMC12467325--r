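# Small deterministic fixtures shared across test files.

# A tiny reflectance cube with known content: rows x cols x bands.
tiny_cube <- function(rows = 8, cols = 8, wavelengths = seq(500, 600, 5),
                      value = NULL, seed = 1) {
  n <- rows * cols * length(wavelengths)
  data <- if (is.null(value)) {
    withr::with_seed(seed, array(runif(n, 0.05, 1.0),
                                 dim = c(rows, cols, length(wavelengths))))
  } else {
    array(value, dim = c(rows, cols, length(wavelengths)))
  }
  spectral_cube(data, wavelengths, "REFLECTANCE")
}

# A small analysis config used where full 128x128 cores are unnecessary.
small_config <- function(...) {
  pipeline_config(shape = c(64, 64), n_cells = 12, noise_sd = 0, ...)
}
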