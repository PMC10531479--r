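# Synthetic dataset generator: assembly, determinism, factor model

test_that("cores are valid structures of the expected size", {
  cage <- fd_core("cage")
  m <- parse_molecules(cage$smiles)
  expect_equal(m$props$formula, "C20H20")
  expect_equal(topological_diameter(m), 5L)      # dodecahedral graph diameter
  c60 <- fd_core("c60")
  m60 <- parse_molecules(c60$smiles)
  expect_equal(m60$props$formula, "C60")
  expect_equal(topological_diameter(m60), 9L)    # truncated icosahedron
  expect_equal(sum(c60$capacity), 0L)            # no substitution sites
})

test_that("assembly attaches exactly the requested motifs", {
  core <- fd_core("cage")
  # empty group list: core unchanged
  expect_identical(assemble_smiles(core, character(0)), core$smiles)
  # four ammonium motifs -> four disjoint matches
  s <- assemble_smiles(core, rep("C[NH3+]", 4), seed = 11)
  expect_equal(smarts_count(s, "[NX4+;H3]"), 4L)
  # one nitro motif: exactly one match, formula gains NO2
  s2 <- assemble_smiles(core, "[N+](=O)[O-]", seed = 3)
  expect_equal(smarts_count(s2, "[NX3+](=[OX1])[OX1-]"), 1L)
  f <- parse_molecules(c(core$smiles, s2))$props$formula
  expect_equal(f[2], "C20H19NO2")
})

test_that("aromatic branches do not collide with open core ring labels", {
  s <- assemble_smiles("cage", rep("c1ccc(cc1)[N+](=O)[O-]", 3), seed = 5)
  m <- parse_molecules(s)
  expect_equal(smarts_count(s, "a1aaaaa1"), 3L)
  expect_equal(sum(m$elements[[1]] == "C"), 20L + 3L * 6L)
})

test_that("attachment site exhaustion raises a generation error", {
  expect_fd_error(assemble_smiles("cage", rep("F", 21), seed = 1),
                  "generation")
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- small_config(seed = 99)
  a <- generate_dataset(cfg, compute_descriptors = FALSE)
  b <- generate_dataset(cfg, compute_descriptors = FALSE)
  expect_identical(a$compounds, b$compounds)
  expect_identical(a$responses, b$responses)
  expect_identical(a$ache, b$ache)
})

test_that("split sizes always equal the configured values", {
  for (seed in c(1, 2, 3)) {
    cfg <- generator_config(n_compounds = 25, n_train = 18, seed = seed)
    ds <- generate_dataset(cfg, compute_descriptors = FALSE)
    expect_equal(sum(ds$compounds$split == "train"), 18L)
    expect_equal(sum(ds$compounds$split == "test"), 7L)
    expect_false(anyDuplicated(ds$compounds$id) > 0)
  }
})

test_that("every generated SMILES parses and ids are unique", {
  ds <- small_dataset()
  m <- parse_molecules(ds$compounds$smiles, ds$compounds$id)
  expect_equal(length(m), nrow(ds$compounds))
  expect_true(all(vapply(m$elements, length, integer(1)) >= 20L))
})

test_that("zero noise with loadings on one factor makes responses perfectly correlated", {
  A <- default_factor_loadings()
  A[, 1] <- seq(0.5, 1.6, length.out = 12)   # distinct affine maps of f1
  A[, 2] <- 0
  cfg <- generator_config(n_compounds = 200, n_train = 150, seed = 4,
                          factor_loadings = A,
                          noise_sd = rep(0, 12))
  ds <- generate_dataset(cfg, compute_descriptors = FALSE)
  R <- cor(as.matrix(ds$responses))
  expect_true(all(abs(R - 1) < 1e-12))
})

test_that("median pairwise response correlation lies in the study window", {
  cfg <- generator_config(n_compounds = 600, n_train = 450, seed = 8)
  ds <- generate_dataset(cfg, compute_descriptors = FALSE)
  R <- cor(as.matrix(ds$responses))
  off <- R[upper.tri(R)]
  expect_gte(median(off), 0.55)
  expect_lte(median(off), 0.98)
})

test_that("responses sit on the binding-score scale with pristine cores lowest", {
  cfg <- generator_config(n_compounds = 120, n_train = 90, seed = 21,
                          p_pristine = 0.15)
  ds <- generate_dataset(cfg, compute_descriptors = FALSE)
  Y <- as.matrix(ds$responses)
  expect_gt(min(Y), 3200); expect_lt(max(Y), 8800)
  pristine <- rowSums(ds$group_counts) == 0
  expect_gte(sum(pristine), 1L)
  expect_lt(max(ds$responses$AvgBScore[pristine]), 5000)
  expect_lt(mean(ds$responses$AvgBScore[pristine]),
            mean(ds$responses$AvgBScore[!pristine]))
})

test_that("configuration contracts are enforced", {
  expect_fd_error(generator_config(n_compounds = 10, n_train = 10), "config")
  expect_fd_error(generator_config(p_pristine = 1.5), "config")
  expect_fd_error(generator_config(noise_sd = rep(-1, 12)), "config")
  g <- default_group_grammar()
  g$prob[2] <- 2
  expect_fd_error(generator_config(grammar = g), "config")
  g2 <- default_group_grammar()
  g2$branch[3] <- "C(=Q)"
  err <- tryCatch(generator_config(grammar = g2), error = identity)
  expect_s3_class(err, "fdtox_config")
  expect_match(conditionMessage(err), "ammonium")   # names the motif
})

test_that("datasets round-trip through CSV with the recorded split honored", {
  ds <- small_dataset()
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path, compute_descriptors = FALSE)
  expect_identical(back$compounds$split, ds$compounds$split)
  expect_equal(as.matrix(back$responses), as.matrix(ds$responses),
               tolerance = 1e-12, ignore_attr = TRUE)
  # a missing response column is named in the error
  tab <- read.csv(path, check.names = FALSE)
  tab$P3ERT <- NULL
  path2 <- tempfile(fileext = ".csv")
  write.csv(tab, path2, row.names = FALSE)
  err <- tryCatch(read_dataset(path2, compute_descriptors = FALSE),
                  error = identity)
  expect_s3_class(err, "fdtox_data")
  expect_match(conditionMessage(err), "P3ERT")
})
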