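# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# a small but learnable corpus: 6 species, ~80 recordings
small_corpus <- function() {
  if (is.null(.fixture_env$small)) {
    scene <- scene_config(n_species = 6, max_count = 16, min_count = 10,
                          noise_fraction = 0.1, seed = 101)
    .fixture_env$small <- generate_dataset(scene)
  }
  .fixture_env$small
}

# tiny corpus for plumbing tests: 4 species, a handful of recordings
tiny_corpus <- function() {
  if (is.null(.fixture_env$tiny)) {
    scene <- scene_config(n_species = 4, max_count = 6, min_count = 5,
                          noise_fraction = 0.2, seed = 202)
    .fixture_env$tiny <- generate_dataset(scene)
  }
  .fixture_env$tiny
}

tiny_vocab <- function() class_vocabulary(c("spA", "spB", "spC"))
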