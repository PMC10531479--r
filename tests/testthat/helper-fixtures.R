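# Shared fixtures. The small dataset is generated once per test run and
# reused; tests that need specific generator conditions build their own
# configs.

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 7, ...) {
  generator_config(n_compounds = 36L, n_train = 27L, seed = seed, ...)
}

# 36-compound dataset with descriptors, cached across test files.
small_dataset <- function() {
  if (is.null(.fixtures$small_ds))
    .fixtures$small_ds <- generate_dataset(small_config())
  .fixtures$small_ds
}

# fast CPANN settings for registry-level tests
small_registry_params <- function() {
  list(dcw = list(epochs = 8L, seed = 1L),
       cpann = list(grid = 6L, epochs = 60L, seed = 1L,
                    all_grid = 8L, all_epochs = 80L))
}

expect_fd_error <- function(expr, kind) {
  expect_error(expr, class = paste0("fdtox_", kind))
}

# Full study-dimension dataset (169 compounds, 127/42 split, descriptors),
# generated once and shared by the acceptance blocks.
study_dataset <- function() {
  if (is.null(.fixtures$study_ds))
    .fixtures$study_ds <- generate_dataset(generator_config(seed = 1))
  .fixtures$study_ds
}
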