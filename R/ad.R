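# Leverage-based applicability domain with Williams-plot export: structural
# outliers flagged by leverage above the warning threshold h* = 3(p+1)/n,
# response outliers by |standardized residual| > 3.

#' Leverage values against a training design
#'
#' Training leverages are the diagonal of the hat matrix
#' `X (X'X)^-1 X'` of the intercept-augmented design; query leverages are the
#' quadratic form `x' (X'X)^-1 x` of query rows against the training design.
#'
#' @param X_train numeric matrix/data frame of training predictors.
#' @param X_query optional matrix of query predictors (default: the training
#'   rows themselves).
#' @return numeric vector of leverages.
#' @export
leverages <- function(X_train, X_query = NULL) {
  Xt <- cbind(1, as.matrix(X_train))
  qrd <- qr(Xt)
  if (qrd$rank < ncol(Xt))
    fd_stop("singularity",
            "training design is rank deficient (rank %d of %d)",
            qrd$rank, ncol(Xt))
  XtXinv <- chol2inv(qr.R(qrd))
  Xq <- if (is.null(X_query)) Xt else cbind(1, as.matrix(X_query))
  fd_assert(ncol(Xq) == ncol(Xt), "dimension",
            "query has %d predictor(s); training design has %d",
            ncol(Xq) - 1, ncol(Xt) - 1)
  rowSums((Xq %*% XtXinv) * Xq)
}

#' Warning leverage threshold
#'
#' The customary Williams-plot cutoff `h* = 3 (p + 1) / n`.
#'
#' @param n number of training compounds.
#' @param p number of model predictors.
#' @param factor multiplier (default 3).
#' @return a number.
#' @examples
#' warning_leverage(127, 2)   # 3 * 3 / 127
#' @export
warning_leverage <- function(n, p, factor = 3) {
  fd_assert(n > p + 1, "parameter",
            "need n > p + 1 (n = %d, p = %d)", n, p)
  factor * (p + 1) / n
}

#' Williams-plot data for a regression model
#'
#' Computes, for every compound in the dataset, the leverage against the
#' model's training design and the standardized residual (residual divided by
#' the training residual SD with `p + 1` degrees-of-freedom correction), and
#' flags structural outliers (`h > h*`) and response outliers
#' (`|std. residual| > sigma_limit`).
#'
#' @param model an `fd_ols` from \code{\link{fit_ols}}.
#' @param X predictor matrix for all compounds (train and test rows).
#' @param y observed response for all compounds.
#' @param split character vector of "train"/"test" labels.
#' @param ids optional compound identifiers.
#' @param sigma_limit response-outlier bound in SD units (default 3).
#' @return an object of class `williams`: per-compound table plus `h_star`.
#' @export
williams <- function(model, X, y, split, ids = NULL,
                     sigma_limit = 3) {
  fd_assert(inherits(model, "fd_ols"), "parameter",
            "model must come from fit_ols()")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  X <- X[, model$predictors, drop = FALSE]
  fd_assert(nrow(X) == length(y) && length(y) == length(split), "dimension",
            "X, y and split must agree in length")
  if (is.null(ids)) ids <- paste0("obj", seq_along(y))
  train <- split == "train"
  fd_assert(sum(train) == model$n, "dimension",
            "split marks %d training rows but the model was fit on %d",
            sum(train), model$n)

  p <- length(model$predictors)
  h <- numeric(length(y))
  h[train] <- leverages(X[train, , drop = FALSE])
  if (any(!train))
    h[!train] <- leverages(X[train, , drop = FALSE],
                           X[!train, , drop = FALSE])

  res <- y - predict(model, X)
  s <- sqrt(sum(model$residuals^2) / (model$n - p - 1))
  std_res <- res / s
  h_star <- warning_leverage(model$n, p)

  tab <- data.frame(
    id = ids, set = ifelse(train, "train", "test"),
    leverage = h, std_residual = std_res,
    structural_outlier = h > h_star,
    response_outlier = abs(std_res) > sigma_limit,
    stringsAsFactors = FALSE)
  structure(list(table = tab, h_star = h_star, sigma_limit = sigma_limit,
                 p = p, n_train = model$n), class = "williams")
}

#' @export
print.williams <- function(x, ...) {
  cat("Williams plot data: ", nrow(x$table), " compounds, h* = ",
      round(x$h_star, 5), ", +/-", x$sigma_limit, " sigma\n", sep = "")
  n_s <- sum(x$table$structural_outlier)
  n_r <- sum(x$table$response_outlier)
  cat("  structural outliers (h > h*): ", n_s, "\n", sep = "")
  cat("  response outliers (|std res| > ", x$sigma_limit, "): ", n_r, "\n",
      sep = "")
  flagged <- x$table$id[x$table$structural_outlier | x$table$response_outlier]
  if (length(flagged) > 0)
    cat("  flagged: ", paste(utils::head(flagged, 15), collapse = ", "),
        if (length(flagged) > 15) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Williams plot
#'
#' Standardized residuals versus leverage, with the warning leverage h* and
#' the +/- sigma bounds drawn; train and test compounds are distinguished.
#'
#' @param x a `williams` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.williams <- function(x, ...) {
  tab <- x$table
  graphics::plot(tab$leverage, tab$std_residual,
                 pch = ifelse(tab$set == "train", 19, 1),
                 col = ifelse(tab$structural_outlier | tab$response_outlier,
                              "red3", "grey30"),
                 xlab = "leverage h", ylab = "standardized residual", ...)
  graphics::abline(v = x$h_star, lty = 2)
  graphics::abline(h = c(-x$sigma_limit, x$sigma_limit), lty = 3)
  graphics::legend("topright", pch = c(19, 1), legend = c("train", "test"),
                   bty = "n")
  invisible(x)
}
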