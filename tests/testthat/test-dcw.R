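# DCW optimal descriptor: weight lookup, Monte-Carlo optimization, calibration

# training set with varied token composition
dcw_smiles <- c("CCN", "CCCN", "CCO", "CCCO", "CCC", "CCCC", "CCNCC",
                "CCOC", "CNC", "COC", "CCCCN", "CCCCO", "NCCN", "OCCO")

test_that("dcw_value is the weighted attribute sum with sub-threshold weights at zero", {
  model <- structure(list(weights = c(C = 1.0, O = 2.0, N = 0.0),
                          active = c("C", "O"), order = 1L, threshold = 3L,
                          calibration = c(intercept = 0, slope = 1)),
                     class = "dcw")
  expect_equal(as.numeric(dcw_value(c(C = 2L, O = 1L), model)), 4.0)
  # sub-threshold attribute (weight 0) contributes nothing
  expect_equal(as.numeric(dcw_value(c(C = 2L, O = 1L, N = 5L), model)), 4.0)
  # unknown attributes contribute 0 and are counted
  v <- dcw_value(c(C = 1L, `[NH3+]` = 2L), model)
  expect_equal(as.numeric(v), 1.0)
  expect_equal(attr(v, "n_unknown"), 1L)
  # all-zero weights give zero
  model$weights[] <- 0
  expect_equal(as.numeric(dcw_value(c(C = 3L, O = 2L), model)), 0.0)
})

test_that("optimization reaches |r| = 1 when the endpoint is one attribute count", {
  y <- vapply(dcw_smiles,
              function(s) sum(smiles_tokens(s) == "N") * 2 + 1, numeric(1))
  fit <- dcw(dcw_smiles, y, order = 1, threshold = 2, epochs = 40, seed = 5)
  expect_gte(fit$train_r, 1 - 1e-9)
})

test_that("accepted-move training |r| is non-decreasing and improves on the start", {
  y <- vapply(dcw_smiles,
              function(s) sum(smiles_tokens(s) == "O") - 0.5 *
                sum(smiles_tokens(s) == "C"), numeric(1))
  fit <- dcw(dcw_smiles, y, order = 1, threshold = 2, epochs = 25, seed = 2)
  expect_false(is.unsorted(fit$r_trace))
  expect_gte(fit$train_r, fit$r_trace[1])
})

test_that("fits are identical for identical seeds and differ in trajectory across seeds", {
  y <- seq_along(dcw_smiles) + rep(c(0, 1), length.out = length(dcw_smiles))
  a <- dcw(dcw_smiles, y, epochs = 10, seed = 3)
  b <- dcw(dcw_smiles, y, epochs = 10, seed = 3)
  expect_identical(a$weights, b$weights)
  expect_identical(a$calibration, b$calibration)
})

test_that("prediction uses frozen weights and calibration (no leakage)", {
  y <- vapply(dcw_smiles,
              function(s) sum(smiles_tokens(s) == "N") * 3, numeric(1))
  fit <- dcw(dcw_smiles, y, order = 1, threshold = 2, epochs = 20, seed = 1)
  w_before <- fit$weights
  test_smi <- c("NCCCN", "CCCCC")
  p1 <- predict(fit, test_smi)
  p2 <- predict(fit, rev(test_smi))
  expect_identical(fit$weights, w_before)
  expect_equal(p1, rev(p2))
})

test_that("parameter recovery: attribute-linear endpoints give training R2 >= 0.9", {
  set.seed(10)
  M <- attribute_matrix <- sapply(c("N", "O", "C"), function(tok)
    vapply(dcw_smiles, function(s) sum(smiles_tokens(s) == tok), numeric(1)))
  beta <- c(3, -2, 0.5)
  y <- as.numeric(M %*% beta) + rnorm(length(dcw_smiles), 0, 0.05)
  fit <- dcw(dcw_smiles, y, order = 1, threshold = 2, epochs = 60, seed = 4)
  expect_gte(fit$train_r^2, 0.9)
})

test_that("degenerate inputs raise the named errors", {
  y <- seq_along(dcw_smiles)
  expect_fd_error(dcw(dcw_smiles[1:5], y[1:5]), "parameter")     # < 10
  expect_fd_error(dcw(dcw_smiles, rep(1, length(dcw_smiles))), "metric")
  expect_fd_error(dcw(dcw_smiles, y, threshold = 999L), "optimization")
})

test_that("models serialize to JSON and the file carries the weights", {
  y <- seq_along(dcw_smiles)
  fit <- dcw(dcw_smiles, y, epochs = 5, seed = 1)
  path <- tempfile(fileext = ".json")
  write_dcw(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$order, fit$order)
  expect_equal(unlist(back$weights[fit$active]),
               fit$weights[fit$active], tolerance = 1e-12,
               ignore_attr = TRUE)
})
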