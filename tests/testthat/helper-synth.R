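# Shared synthetic fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

default_library <- function() memo("lib", make_library(1))

# the standard study conditions: 80 samples, default generator
default_dataset <- function() {
  memo("data80", generate_dataset(default_library(), synthetic_config(seed = 2)))
}

default_split <- function() memo("split80", random_split(default_dataset(), 60, seed = 3))

calibration_set <- function() {
  memo("cal", subset_samples(default_dataset(), default_split()$calibration_ids))
}
prediction_set <- function() {
  memo("pred", subset_samples(default_dataset(), default_split()$prediction_ids))
}

# a small, quickly trainable model for structural tests
small_trained_cae <- function() {
  memo("small_cae", {
    d <- generate_dataset(default_library(),
                          synthetic_config(n_samples = 14, seed = 9))
    train_cae(build_cae(cae_config(latent_dim = 8, max_epochs = 2, seed = 4)),
              d, seed = 4)
  })
}

tiny_cae_config <- function(seed = 5) {
  cae_config(input_length = 8, kernel_size = 3, decoder_kernel_size = 3,
             latent_dim = 2, encoder_filters = c(2, 2), dense_hidden = 3,
             seed = seed)
}
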