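# Counter-propagation ANN: training behaviour, lookup prediction, LOO-CV, maps

# hand-built 2 x 2 network with identity normalization, for lookup contracts
manual_net <- function(W, U) {
  p <- ncol(W); r <- ncol(U)
  structure(list(
    input_weights = W, output_weights = U, grid = 2L,
    norm_x = list(min = rep(0, p), span = rep(1, p), names = colnames(W)),
    norm_y = list(min = rep(0, r), span = rep(1, r), names = colnames(U)),
    x_names = colnames(W) %||% paste0("x", seq_len(p)),
    y_names = colnames(U) %||% paste0("y", seq_len(r)),
    qe = 0, epochs = 1L, lr = c(0.5, 0.01), seed = 1L, n_train = 0L),
    class = "cpann")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("BMU returns the matching neuron with zero distance and breaks ties row-major", {
  W <- rbind(c(0.1, 0.1), c(0.9, 0.1), c(0.1, 0.9), c(0.9, 0.9))
  U <- matrix(1:4 / 4, 4, 1)
  net <- manual_net(W, U)
  b <- best_matching_unit(net, c(0.1, 0.9))       # neuron 3 = row 2, col 1
  expect_equal(b$index, 3L)
  expect_equal(c(b$row, b$col), c(2L, 1L))
  # exact tie between neurons 2 and 3: lowest row-major index wins
  tieW <- rbind(c(0, 0), c(0.5, 0.5), c(0.5, 0.5), c(1, 1))
  tie <- manual_net(tieW, U)
  expect_equal(best_matching_unit(tie, c(0.5, 0.5))$index, 2L)
})

test_that("BMU is invariant under a consistent permutation of descriptors", {
  W <- matrix(runif(8), 4, 2)
  net1 <- manual_net(W, matrix(1:4, 4, 1))
  net2 <- manual_net(W[, 2:1], matrix(1:4, 4, 1))
  x <- c(0.3, 0.8)
  expect_equal(best_matching_unit(net1, x)$index,
               best_matching_unit(net2, rev(x))$index)
})

test_that("training is deterministic and keeps weights in the normalized hull", {
  set.seed(5)
  X <- matrix(runif(50 * 3), 50)
  Y <- cbind(rowSums(X) + rnorm(50, 0, 0.1))
  a <- cpann(X, Y, grid = 5, epochs = 40, seed = 9)
  b <- cpann(X, Y, grid = 5, epochs = 40, seed = 9)
  expect_identical(a$input_weights, b$input_weights)
  expect_identical(a$output_weights, b$output_weights)
  expect_true(all(a$input_weights >= 0 & a$input_weights <= 1))
  expect_true(all(a$output_weights >= 0 & a$output_weights <= 1))
})

test_that("quantization error at the final epoch does not exceed its first-epoch value", {
  set.seed(6)
  ok <- vapply(1:5, function(s) {
    X <- matrix(runif(40 * 2), 40)
    Y <- cbind(X[, 1] + 0.2 * X[, 2])
    net <- cpann(X, Y, grid = 5, epochs = 50, seed = s)
    net$qe[length(net$qe)] <= net$qe[1]
  }, logical(1))
  expect_true(all(ok))
})

test_that("a 1 x 1 grid maps everything to one neuron whose outputs approach the response means", {
  set.seed(2)
  X <- matrix(runif(30 * 2), 30)
  Y <- cbind(a = rnorm(30, 5, 1), b = rnorm(30, -2, 0.5))
  net <- cpann(X, Y, grid = 1, epochs = 200, lr = c(0.5, 0.001), seed = 1)
  b <- best_matching_unit(net, X)
  expect_true(all(b$index == 1L))
  pred <- suppressWarnings(predict(net, X))
  expect_equal(unname(pred[1, ]), unname(colMeans(Y)),
               tolerance = 0.15 * max(apply(Y, 2, function(v) diff(range(v)))))
})

test_that("prediction is a pure lookup and a single-object set reproduces its target", {
  X <- matrix(c(0.3, 0.7), 1)
  Y <- matrix(42, 1, 1)
  net <- cpann(X, Y, grid = 3, epochs = 120, seed = 3)
  p1 <- suppressWarnings(predict(net, X))
  p2 <- suppressWarnings(predict(net, X))
  expect_identical(p1, p2)
  # the lone training object's target is recovered (constant column: exact)
  expect_equal(unname(p1), 42, tolerance = 1e-8)
})

test_that("training objects are predicted within a small normalized error after heavy training", {
  set.seed(8)
  X <- matrix(runif(60 * 2), 60)
  Y <- cbind(y = X[, 1]^2 + X[, 2])
  net <- cpann(X, Y, grid = 8, epochs = 150, seed = 4)
  pred <- suppressWarnings(predict(net, X))
  err_norm <- abs(pred - Y[, 1]) / diff(range(Y[, 1]))
  expect_lt(mean(err_norm), 0.15)
})

test_that("objects with identical descriptor rows share a BMU and map exports conserve objects", {
  set.seed(12)
  X <- matrix(runif(20 * 2), 20)
  X[20, ] <- X[1, ]
  Y <- cbind(rowSums(X))
  net <- cpann(X, Y, grid = 4, epochs = 30, seed = 2)
  maps <- cpann_maps(net, X, ids = paste0("c", 1:20))
  expect_equal(nrow(maps$top), 20L)
  expect_equal(maps$top$index[20], maps$top$index[1])
  expect_equal(dim(maps$weight_maps)[3], 2L)
  expect_equal(dim(maps$output_maps)[3], 1L)
})

test_that("LOO-CV predicts duplicated objects from their twins", {
  set.seed(3)
  base <- matrix(runif(6 * 2), 6)
  X <- base[rep(1:6, each = 3), ] + rnorm(36, 0, 1e-4)
  y <- rowSums(X[, 1:2]) * 10
  loo <- cpann_loo(X, cbind(y = y), grid = 4, epochs = 60, seed = 1)
  expect_gte(unname(loo$q2cv["y"]), 0.95)
  expect_gte(unname(loo$q2cv_press["y"]), 0.9)
})

test_that("parameter and data contracts raise the named errors", {
  X <- matrix(runif(20), 10, 2)
  Y <- cbind(rnorm(10))
  expect_fd_error(cpann(X, Y, grid = 0), "parameter")
  expect_fd_error(cpann(X, Y, epochs = 0), "parameter")
  Xna <- X; Xna[3, 1] <- NA
  err <- tryCatch(cpann(Xna, Y), error = identity)
  expect_s3_class(err, "fdtox_data")
  expect_match(conditionMessage(err), "3")      # offending row is listed
  expect_fd_error(cpann_loo(X[1:2, ], Y[1:2, , drop = FALSE]), "parameter")
  expect_fd_error(cpann_loo(X, cbind(rep(1, 10))), "metric")
  expect_fd_error(predict(cpann(X, Y, grid = 2, epochs = 5), X[, 1, drop = FALSE]),
                  "dimension")
})

test_that("out-of-range queries are clipped with a warning, not an error", {
  X <- matrix(runif(30), 15, 2)
  net <- cpann(X, cbind(rowSums(X)), grid = 3, epochs = 20, seed = 1)
  expect_warning(predict(net, matrix(c(5, -3), 1)), "clipped")
})
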