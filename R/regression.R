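# Ordinary-least-squares QSAR models, the six-entry model registry, and the
# Pearson correlation analysis of responses and descriptors.

#' Fit an ordinary least squares model
#'
#' Least-squares fit of `y` on the columns of `X` with an intercept. The
#' training R^2 is the squared Pearson correlation between observed and fitted
#' values, RMSE the root mean squared residual.
#'
#' @param X numeric matrix or data frame of predictors.
#' @param y numeric response.
#' @param ids optional observation identifiers stored with the model.
#' @return an object of class `fd_ols` with coefficients, fitted values and
#'   training metrics.
#' @export
fit_ols <- function(X, y, ids = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fd_assert(nrow(X) == length(y), "dimension",
            "X has %d rows but y has length %d", nrow(X), length(y))
  fd_assert(all(is.finite(X)) && all(is.finite(y)), "data",
            "non-finite values in the design matrix or response")
  p <- ncol(X)
  fd_assert(nrow(X) > p + 1, "parameter",
            "need n > p + 1 observations (n = %d, p = %d)", nrow(X), p)
  fd_assert(stats::sd(y) > 0, "metric", "response is constant")

  D <- cbind(`(Intercept)` = 1, X)
  qrd <- qr(D)
  if (qrd$rank < ncol(D)) {
    dropped <- colnames(D)[qrd$pivot[(qrd$rank + 1):ncol(D)]]
    fd_stop("singularity", "design matrix is rank deficient; collinear: %s",
            paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(D, y)
  fitted <- as.numeric(D %*% fit$coefficients)
  structure(list(
    coefficients = fit$coefficients[-1],
    intercept = unname(fit$coefficients[1]),
    predictors = colnames(X),
    fitted = fitted, residuals = y - fitted, y = y,
    r2 = suppressWarnings(q2_pearson(y, fitted)),
    rmse = rmse(y, fitted),
    n = nrow(X), ids = ids), class = "fd_ols")
}

#' @export
print.fd_ols <- function(x, ...) {
  cat("OLS model: ", length(x$predictors), " predictor(s), n = ", x$n,
      "\n", sep = "")
  print(round(c(`(Intercept)` = x$intercept, x$coefficients), 5))
  cat("training R2 = ", round(x$r2, 4), ", RMSE = ", signif(x$rmse, 5),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.fd_ols <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.fd_ols <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$predictors, drop = FALSE]
  as.numeric(object$intercept + X %*% object$coefficients)
}

#' @export
summary.fd_ols <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Evaluate a fitted model on new data
#'
#' Reports the external Q^2 under both definitions used in the QSAR
#' literature: the squared Pearson correlation between observed and predicted
#' (which is invariant to affine miscalibration -- a constant shift still
#' yields 1), and the PRESS-based form `1 - sum((obs-pred)^2) /
#' sum((obs - mean(train y))^2)`, plus the RMSE.
#'
#' @param model an `fd_ols`, `cpann`, or `dcw` model.
#' @param newdata descriptor matrix / SMILES vector for the evaluation set.
#' @param y_new observed responses of the evaluation set.
#' @return named numeric vector `c(q2, q2_press, rmse)`.
#' @export
evaluate <- function(model, newdata, y_new) {
  pred <- if (inherits(model, "dcw")) predict(model, newdata)
          else predict(model, newdata)
  pred <- as.numeric(pred)
  fd_assert(length(pred) == length(y_new), "dimension",
            "predictions (%d) and y_new (%d) differ in length",
            length(pred), length(y_new))
  ref_mean <- if (inherits(model, "fd_ols")) mean(model$y) else mean(y_new)
  c(q2 = q2_pearson(y_new, pred),
    q2_press = q2_press(y_new, pred, ref_mean),
    rmse = rmse(y_new, pred))
}

#' Pearson correlation matrix
#'
#' @param x data frame or matrix of numeric columns (responses and/or
#'   descriptors).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  X <- as.matrix(x)
  fd_assert(ncol(X) >= 2, "parameter", "need at least two columns")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    fd_stop("metric", "constant column(s): %s",
            paste(colnames(X)[sds == 0], collapse = ", "))
  stats::cor(X)
}

#' Fit the six-model registry
#'
#' Fits, per response, the six model families of the study design:
#' \describe{
#'   \item{ALL_regression}{OLS on all 28 descriptors (25 drug-like + QPpolrz +
#'     TD + DCW).}
#'   \item{ALL_CPANN}{one multi-output CPANN on the same 28 descriptors.}
#'   \item{regression_1}{OLS on QPpolrz + TD.}
#'   \item{regression_2}{OLS on the endpoint-specific DCW descriptor.}
#'   \item{cpann_1}{CPANN on QPpolrz + TD.}
#'   \item{cpann_2}{single-input CPANN on the endpoint-specific DCW.}
#' }
#' All models are fitted on the training split and evaluated on the test
#' split. The shared 28th descriptor for the ALL models is the DCW fitted to
#' the average binding score. Constant or aliased predictor columns are
#' dropped from the ALL_regression design (recorded in the result) since
#' synthetic tables can contain invariant descriptor slots.
#'
#' @param dataset an `fd_dataset` with descriptors, responses and split.
#' @param dcw_params list of arguments for \code{\link{dcw}} (order,
#'   threshold, epochs, step, seed).
#' @param cpann_params list with elements `grid`, `epochs`, `seed` for the
#'   prediction CPANNs (defaults 14, 400, 1), `all_grid`, `all_epochs` for the
#'   ALL_CPANN model (defaults 20, 600).
#' @param responses response columns to model (default: all 12).
#' @return an object of class `model_registry`.
#' @export
build_registry <- function(dataset,
                           dcw_params = list(),
                           cpann_params = list(),
                           responses = RESPONSE_NAMES) {
  fd_assert(inherits(dataset, "fd_dataset"), "parameter",
            "dataset must be an fd_dataset")
  fd_assert(!is.null(dataset$descriptors), "registry",
            "dataset has no descriptor table")
  missing_resp <- setdiff(responses, names(dataset$responses))
  fd_assert(length(missing_resp) == 0, "registry",
            "missing response column(s): %s",
            paste(missing_resp, collapse = ", "))
  for (col in c("QPpolrz", "TD"))
    fd_assert(col %in% names(dataset$descriptors), "registry",
              "missing predictor column: %s", col)

  dp <- utils::modifyList(list(order = 2L, threshold = 3L, epochs = 30L,
                               step = 0.1, seed = 1L), dcw_params)
  cp <- utils::modifyList(list(grid = 14L, epochs = 400L, seed = 1L,
                               all_grid = 20L, all_epochs = 600L),
                          cpann_params)

  train <- dataset$compounds$split == "train"
  smi <- dataset$compounds$smiles
  D <- as.matrix(dataset$descriptors)
  Y <- as.matrix(dataset$responses[, responses, drop = FALSE])

  # endpoint-specific DCW models
  dcw_models <- lapply(responses, function(resp)
    dcw(smi[train], Y[train, resp], order = dp$order,
        threshold = dp$threshold, epochs = dp$epochs, step = dp$step,
        seed = dp$seed))
  names(dcw_models) <- responses
  dcw_cols <- vapply(responses, function(resp)
    predict(dcw_models[[resp]], smi, type = "dcw"), numeric(nrow(D)))

  # shared DCW column for the ALL models: the average-binding-score endpoint
  shared_dcw <- dcw_cols[, "AvgBScore"]
  D28 <- cbind(D, DCW = shared_dcw)

  # drop invariant columns from the ALL design (constant on training split)
  const_cols <- colnames(D28)[apply(D28[train, , drop = FALSE], 2,
                                    stats::sd) == 0]
  D28_used <- D28[, setdiff(colnames(D28), const_cols), drop = FALSE]
  # drop aliased columns, if any, by QR pivoting on the training design
  qrd <- qr(cbind(1, D28_used[train, , drop = FALSE]))
  aliased <- character(0)
  if (qrd$rank < ncol(D28_used) + 1) {
    keep_idx <- sort(qrd$pivot[seq_len(qrd$rank)])
    keep_idx <- setdiff(keep_idx, 1L) - 1L
    aliased <- setdiff(colnames(D28_used), colnames(D28_used)[keep_idx])
    D28_used <- D28_used[, colnames(D28_used)[keep_idx], drop = FALSE]
  }

  fit_entry_ols <- function(Xcols) {
    lapply(responses, function(resp) {
      m <- fit_ols(Xcols[train, , drop = FALSE], Y[train, resp],
                   ids = dataset$compounds$id[train])
      ev <- suppressWarnings(
        evaluate(m, Xcols[!train, , drop = FALSE], Y[!train, resp]))
      list(model = m, test = ev)
    })
  }

  entries <- list()
  entries$ALL_regression <- stats::setNames(fit_entry_ols(D28_used),
                                            responses)
  entries$regression_1 <- stats::setNames(
    fit_entry_ols(D28[, c("QPpolrz", "TD"), drop = FALSE]), responses)
  entries$regression_2 <- stats::setNames(lapply(responses, function(resp) {
    Xc <- dcw_cols[, resp, drop = FALSE]
    colnames(Xc) <- "DCW"
    m <- fit_ols(Xc[train, , drop = FALSE], Y[train, resp],
                 ids = dataset$compounds$id[train])
    ev <- suppressWarnings(
      evaluate(m, Xc[!train, , drop = FALSE], Y[!train, resp]))
    list(model = m, test = ev, dcw = dcw_models[[resp]])
  }), responses)

  # CPANN entries
  all_net <- cpann(D28_used[train, , drop = FALSE],
                   Y[train, , drop = FALSE],
                   grid = cp$all_grid, epochs = cp$all_epochs, seed = cp$seed)
  net1 <- cpann(D28[train, c("QPpolrz", "TD"), drop = FALSE],
                Y[train, , drop = FALSE],
                grid = cp$grid, epochs = cp$epochs, seed = cp$seed)

  cpann_entry <- function(net, Xall) {
    pr_tr <- suppressWarnings(predict(net, Xall[train, , drop = FALSE]))
    pr_te <- suppressWarnings(predict(net, Xall[!train, , drop = FALSE]))
    pr_tr <- as.matrix(pr_tr); pr_te <- as.matrix(pr_te)
    stats::setNames(lapply(seq_along(responses), function(j) {
      list(model = net,
           train = c(r2 = suppressWarnings(
                       q2_pearson(Y[train, j], pr_tr[, j])),
                     rmse = rmse(Y[train, j], pr_tr[, j])),
           test = c(q2 = suppressWarnings(
                      q2_pearson(Y[!train, j], pr_te[, j])),
                    q2_press = q2_press(Y[!train, j], pr_te[, j],
                                        mean(Y[train, j])),
                    rmse = rmse(Y[!train, j], pr_te[, j])))
    }), responses)
  }
  entries$ALL_CPANN <- cpann_entry(all_net, D28_used)
  entries$cpann_1 <- cpann_entry(net1, D28[, c("QPpolrz", "TD"),
                                           drop = FALSE])

  entries$cpann_2 <- stats::setNames(lapply(responses, function(resp) {
    Xc <- dcw_cols[, resp, drop = FALSE]
    colnames(Xc) <- "DCW"
    net <- cpann(Xc[train, , drop = FALSE], Y[train, resp, drop = FALSE],
                 grid = cp$grid, epochs = 300L, seed = cp$seed)
    pr_tr <- suppressWarnings(predict(net, Xc[train, , drop = FALSE]))
    pr_te <- suppressWarnings(predict(net, Xc[!train, , drop = FALSE]))
    list(model = net,
         train = c(r2 = suppressWarnings(q2_pearson(Y[train, resp], pr_tr)),
                   rmse = rmse(Y[train, resp], pr_tr)),
         test = c(q2 = suppressWarnings(q2_pearson(Y[!train, resp], pr_te)),
                  q2_press = q2_press(Y[!train, resp], pr_te,
                                      mean(Y[train, resp])),
                  rmse = rmse(Y[!train, resp], pr_te)))
  }), responses)

  structure(list(entries = entries, responses = responses,
                 dropped_columns = c(const_cols, aliased),
                 predictors_all = colnames(D28_used),
                 dcw_models = dcw_models,
                 params = list(dcw = dp, cpann = cp)),
            class = "model_registry")
}

#' Summarize a model registry
#'
#' @param object a `model_registry`.
#' @param ... unused.
#' @return data frame with one row per model x response: training R2/RMSE and
#'   test Q2 (both definitions) / RMSE.
#' @export
summary.model_registry <- function(object, ...) {
  rows <- list()
  for (entry in names(object$entries)) {
    for (resp in object$responses) {
      e <- object$entries[[entry]][[resp]]
      if (inherits(e$model, "fd_ols")) {
        r2 <- e$model$r2; rmse_tr <- e$model$rmse
      } else {
        r2 <- unname(e$train["r2"]); rmse_tr <- unname(e$train["rmse"])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = entry, response = resp, r2_train = r2, rmse_train = rmse_tr,
        q2_test = unname(e$test["q2"]),
        q2_press_test = unname(e$test["q2_press"]),
        rmse_test = unname(e$test["rmse"]))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.model_registry <- function(x, ...) {
  cat("Model registry: ", length(x$entries), " families x ",
      length(x$responses), " responses = ",
      length(x$entries) * length(x$responses), " fitted models\n", sep = "")
  if (length(x$dropped_columns) > 0)
    cat("  dropped invariant/aliased predictor(s): ",
        paste(x$dropped_columns, collapse = ", "), "\n", sep = "")
  s <- summary(x)
  cat("  mean test Q2 by family:\n")
  print(round(tapply(s$q2_test, s$model, mean), 4))
  invisible(x)
}
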