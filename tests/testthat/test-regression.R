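# OLS fitting, evaluation metrics, correlation analysis, model registry

test_that("noiseless line is recovered exactly", {
  x <- matrix(seq(-3, 3, length.out = 20), dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + 1
  m <- fit_ols(x, y)
  expect_equal(unname(m$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-10)
  expect_equal(m$r2, 1, tolerance = 1e-10)
  expect_lt(m$rmse, 1e-10)
})

test_that("pure-noise response yields negligible R2", {
  set.seed(1)
  X <- matrix(rnorm(2000), 1000, 2)
  y <- rnorm(1000)
  expect_lte(fit_ols(X, y)$r2, 0.05)
})

test_that("OLS equals the normal-equations oracle on small instances", {
  set.seed(7)
  for (p in c(1, 2, 3)) {
    n <- 20
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    m <- fit_ols(X, y)
    D <- cbind(1, X)
    beta <- solve(t(D) %*% D, t(D) %*% y)       # brute-force normal equations
    expect_equal(unname(c(m$intercept, m$coefficients)), as.numeric(beta),
                 tolerance = 1e-8)
  }
})

test_that("adding an irrelevant predictor never decreases training R2", {
  set.seed(9)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] - X[, 2] + rnorm(30, 0, 0.5)
  r2_small <- fit_ols(X, y)$r2
  r2_big <- fit_ols(cbind(X, junk = rnorm(30)), y)$r2
  expect_gte(r2_big + 1e-12, r2_small)
})

test_that("degenerate designs raise the named errors", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("A", "B")))
  expect_fd_error(fit_ols(X, rep(1, 20)), "metric")               # constant y
  err <- tryCatch(fit_ols(cbind(X, A2 = X[, "A"]), rnorm(20)), error = identity)
  expect_s3_class(err, "fdtox_singularity")
  expect_match(conditionMessage(err), "A2|A")                     # names column
  expect_fd_error(fit_ols(X[1:3, ], rnorm(3)), "parameter")       # n <= p+1
  Xi <- X; Xi[2, 1] <- Inf
  expect_fd_error(fit_ols(Xi, rnorm(20)), "data")
})

test_that("evaluate reports both Q2 definitions and flags anti-correlation", {
  x <- matrix(seq_len(20), dimnames = list(NULL, "x"))
  y <- 3 * x[, 1] + rnorm(20, 0, 0.01)
  m <- fit_ols(x, y)
  self <- evaluate(m, x, y)
  expect_gte(unname(self["q2"]), 0.999)
  # constant shift: squared-correlation Q2 stays 1, RMSE equals the shift
  shifted <- evaluate(m, x, y + 7)
  expect_equal(unname(shifted["q2"]), 1, tolerance = 1e-6)
  expect_equal(unname(shifted["rmse"]), 7, tolerance = 1e-2)
  expect_lt(unname(shifted["q2_press"]), unname(self["q2_press"]))
  # anti-correlated predictions: high q2 but a warning is emitted
  m_neg <- m
  m_neg$coefficients <- -m$coefficients
  m_neg$intercept <- -m$intercept
  expect_warning(evaluate(m_neg, x, y), "anti-correlated")
})

test_that("correlation matrix is symmetric with unit diagonal and exact limits", {
  set.seed(2)
  x <- rnorm(50)
  tab <- data.frame(a = x, b = -x, c = rnorm(50))
  R <- correlation_matrix(tab)
  expect_equal(diag(R), c(a = 1, b = 1, c = 1))
  expect_equal(R, t(R))
  expect_equal(R["a", "b"], -1)
  expect_true(all(R >= -1 & R <= 1))
  err <- tryCatch(correlation_matrix(data.frame(a = x, k = rep(2, 50))),
                  error = identity)
  expect_s3_class(err, "fdtox_metric")
  expect_match(conditionMessage(err), "k")
})

test_that("registry fits 6 families x 12 responses and is reproducible", {
  ds <- small_dataset()
  reg <- build_registry(ds, dcw_params = small_registry_params()$dcw,
                        cpann_params = small_registry_params()$cpann)
  s <- summary(reg)
  expect_equal(nrow(s), 72L)
  expect_setequal(unique(s$model),
                  c("ALL_regression", "ALL_CPANN", "regression_1",
                    "regression_2", "cpann_1", "cpann_2"))
  expect_true(all(is.finite(s$r2_train)))
  reg2 <- build_registry(ds, dcw_params = small_registry_params()$dcw,
                         cpann_params = small_registry_params()$cpann)
  expect_equal(summary(reg2), s, tolerance = 1e-12)
})

test_that("registry names missing predictor columns", {
  ds <- small_dataset()
  broken <- ds
  broken$descriptors <- ds$descriptors[, setdiff(names(ds$descriptors),
                                                 "QPpolrz")]
  err <- tryCatch(build_registry(broken), error = identity)
  expect_s3_class(err, "fdtox_registry")
  expect_match(conditionMessage(err), "QPpolrz")
})

test_that("fit_ols R2 agrees with the correlation matrix of observed and fitted", {
  set.seed(11)
  X <- matrix(rnorm(80), 40, 2)
  y <- X[, 1] + rnorm(40, 0, 0.3)
  m <- fit_ols(X, y)
  R <- correlation_matrix(data.frame(obs = y, fit = m$fitted))
  expect_equal(m$r2, R["obs", "fit"]^2, tolerance = 1e-12)
})
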