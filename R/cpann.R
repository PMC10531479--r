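# Counter-propagation artificial neural network: a square Kohonen
# self-organizing input layer with a superimposed output layer of the same
# lattice arrangement. Prediction is a pure lookup: the de-normalized output
# weights of the winning neuron.

#' Fit a counter-propagation neural network
#'
#' Trains a `grid x grid` Kohonen lattice on min-max-normalized descriptors
#' `x` with a superimposed output layer holding the (also normalized)
#' responses `y`. Objects are presented in a seeded, re-shuffled order each
#' epoch; the best-matching unit and its neighbourhood (triangular kernel,
#' radius decaying linearly from `grid/2` to 0) move toward the object's
#' descriptor and response vectors with a linearly decaying learning rate.
#'
#' @param x numeric matrix or data frame of descriptors (training objects in
#'   rows), no missing values.
#' @param y numeric vector, matrix or data frame of one or more responses.
#' @param grid lattice side length (default 14).
#' @param epochs number of training epochs (default 400).
#' @param lr learning-rate bounds `c(lr_max, lr_min)`.
#' @param seed integer seed; fixed seed gives identical weight tensors.
#' @return an object of class `cpann` with the trained input/output weight
#'   matrices, the per-epoch quantization error, and the normalization ranges.
#' @seealso \code{\link{predict.cpann}}, \code{\link{cpann_loo}},
#'   \code{\link{cpann_maps}}
#' @export
cpann <- function(x, y, grid = 14L, epochs = 400L, lr = c(0.5, 0.01),
                  seed = 1L) {
  fd_assert(is.numeric(grid) && length(grid) == 1 && grid >= 1, "parameter",
            "grid must be a positive integer")
  fd_assert(is.numeric(epochs) && length(epochs) == 1 && epochs >= 1,
            "parameter", "epochs must be a positive integer")
  fd_assert(length(lr) == 2 && all(lr > 0) && all(lr <= 1) && lr[1] >= lr[2],
            "parameter", "lr must be c(lr_max, lr_min) within (0, 1]")
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  Y <- as.matrix(y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  fd_assert(nrow(X) == nrow(Y), "dimension",
            "x has %d rows but y has %d", nrow(X), nrow(Y))
  bad <- which(!stats::complete.cases(X) | !stats::complete.cases(Y))
  if (length(bad) > 0)
    fd_stop("data", "missing values in row(s): %s",
            paste(utils::head(bad, 10), collapse = ", "))
  fd_assert(ncol(Y) >= 1, "data", "at least one response column required")

  nx <- minmax_fit(X)
  ny <- minmax_fit(Y)
  Xn <- minmax_apply(X, nx)
  Yn <- minmax_apply(Y, ny)

  set.seed(seed)
  fit <- .cpann_train_cpp(Xn, Yn, as.integer(grid), as.integer(epochs),
                          lr[1], lr[2])

  structure(list(
    input_weights = fit$input_weights, output_weights = fit$output_weights,
    qe = as.numeric(fit$qe), grid = as.integer(grid),
    epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
    norm_x = nx, norm_y = ny,
    x_names = colnames(X), y_names = colnames(Y),
    n_train = nrow(X)), class = "cpann")
}

#' @export
print.cpann <- function(x, ...) {
  cat("Counter-propagation ANN\n")
  cat("  lattice: ", x$grid, " x ", x$grid, " neurons; ", x$epochs,
      " epochs; lr ", x$lr[1], " -> ", x$lr[2], "\n", sep = "")
  cat("  inputs:  ", length(x$x_names), " descriptor(s)\n", sep = "")
  cat("  outputs: ", length(x$y_names), " response(s)\n", sep = "")
  cat("  final quantization error: ", signif(x$qe[length(x$qe)], 4), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.cpann <- function(object, ...) {
  cat("Counter-propagation ANN (", object$grid, " x ", object$grid, ", ",
      object$epochs, " epochs, seed ", object$seed, ")\n", sep = "")
  cat("Quantization error: epoch 1 = ", signif(object$qe[1], 4),
      ", final = ", signif(object$qe[length(object$qe)], 4), "\n", sep = "")
  cat("Responses: ", paste(object$y_names, collapse = ", "), "\n", sep = "")
  invisible(object)
}

normalize_query <- function(object, newdata) {
  Xq <- as.matrix(newdata)
  if (is.null(dim(newdata)) && length(newdata) == length(object$x_names))
    Xq <- matrix(as.numeric(newdata), nrow = 1)
  fd_assert(ncol(Xq) == length(object$x_names), "dimension",
            "query has %d descriptor(s); model expects %d",
            ncol(Xq), length(object$x_names))
  minmax_apply(Xq, object$norm_x, clip = TRUE)
}

#' Best-matching unit of a query object
#'
#' @param model a fitted `cpann`.
#' @param x one descriptor vector (raw units) or a matrix of them.
#' @return data frame with the 1-based lattice `row`, `col` and row-major
#'   `index` of the winning neuron for each query row. Ties are broken by the
#'   lowest row-major index.
#' @export
best_matching_unit <- function(model, x) {
  fd_assert(inherits(model, "cpann"), "state", "model is not a fitted cpann")
  Xn <- normalize_query(model, x)
  k <- .cpann_bmu_cpp(model$input_weights, Xn, model$grid)
  data.frame(row = (k - 1L) %/% model$grid + 1L,
             col = (k - 1L) %% model$grid + 1L,
             index = k)
}

#' Predict responses with a trained CPANN
#'
#' Pure lookup: the de-normalized output-weight vector of each query's
#' best-matching unit. Query descriptors outside the training range are
#' clipped to the normalized hull with a warning.
#'
#' @param object a fitted `cpann`.
#' @param newdata descriptor matrix/data frame (or a single vector).
#' @param ... unused.
#' @return numeric matrix (queries x responses); a vector for a
#'   single-response model.
#' @export
predict.cpann <- function(object, newdata, ...) {
  fd_assert(!is.null(object$input_weights), "state", "model is not trained")
  Xn <- normalize_query(object, newdata)
  k <- .cpann_bmu_cpp(object$input_weights, Xn, object$grid)
  Un <- object$output_weights[k, , drop = FALSE]
  out <- minmax_invert(Un, object$norm_y)
  colnames(out) <- object$y_names
  rownames(out) <- rownames(newdata)
  if (ncol(out) == 1L) out[, 1L] else out
}

#' Leave-one-out cross-validation for a CPANN
#'
#' Retrains the network `n` times, each time leaving out one object and
#' predicting it, and reports per-response LOO statistics under both Q^2
#' definitions (squared Pearson correlation, and the PRESS-based form against
#' the full-set response mean).
#'
#' @inheritParams cpann
#' @return an object of class `cpann_loo`: list with `predictions`
#'   (n x responses), `q2cv` (squared-correlation), `q2cv_press`, and `rmsecv`
#'   per response.
#' @export
cpann_loo <- function(x, y, grid = 14L, epochs = 400L, lr = c(0.5, 0.01),
                      seed = 1L) {
  X <- as.matrix(x)
  Y <- as.matrix(y)
  n <- nrow(X)
  fd_assert(n >= 3, "parameter", "leave-one-out needs at least 3 objects")
  for (j in seq_len(ncol(Y)))
    fd_assert(stats::sd(Y[, j]) > 0, "metric",
              "response %s is constant", colnames(Y)[j])
  preds <- matrix(NA_real_, n, ncol(Y))
  for (i in seq_len(n)) {
    fit <- cpann(X[-i, , drop = FALSE], Y[-i, , drop = FALSE], grid = grid,
                 epochs = epochs, lr = lr, seed = seed)
    p <- suppressWarnings(predict(fit, X[i, , drop = FALSE]))
    preds[i, ] <- as.numeric(p)
  }
  colnames(preds) <- colnames(Y)
  q2 <- vapply(seq_len(ncol(Y)), function(j)
    suppressWarnings(q2_pearson(Y[, j], preds[, j])), numeric(1))
  q2p <- vapply(seq_len(ncol(Y)), function(j)
    q2_press(Y[, j], preds[, j], mean(Y[, j])), numeric(1))
  rmse_cv <- vapply(seq_len(ncol(Y)), function(j)
    rmse(Y[, j], preds[, j]), numeric(1))
  structure(list(predictions = preds,
                 q2cv = stats::setNames(q2, colnames(Y)),
                 q2cv_press = stats::setNames(q2p, colnames(Y)),
                 rmsecv = stats::setNames(rmse_cv, colnames(Y)),
                 grid = grid, epochs = epochs, seed = seed),
            class = "cpann_loo")
}

#' @export
print.cpann_loo <- function(x, ...) {
  cat("CPANN leave-one-out cross-validation (", x$grid, " x ", x$grid, ", ",
      x$epochs, " epochs)\n", sep = "")
  print(round(rbind(`Q2cv (r^2)` = x$q2cv, `Q2cv (PRESS)` = x$q2cv_press,
                    RMSEcv = x$rmsecv), 4))
  invisible(x)
}

#' Export the top, weight, and output maps of a trained CPANN
#'
#' @param model a fitted `cpann`.
#' @param x descriptor matrix of the objects to place on the top map.
#' @param ids optional object identifiers.
#' @return an object of class `cpann_maps`: `top` (one row per object with its
#'   winning neuron), `weight_maps` (grid x grid x descriptors), and
#'   `output_maps` (grid x grid x responses, de-normalized).
#' @export
cpann_maps <- function(model, x, ids = rownames(x)) {
  fd_assert(inherits(model, "cpann"), "state", "model is not a fitted cpann")
  Xq <- as.matrix(x)
  if (is.null(ids)) ids <- paste0("obj", seq_len(nrow(Xq)))
  top <- best_matching_unit(model, Xq)
  top <- cbind(data.frame(id = ids), top)
  g <- model$grid
  p <- length(model$x_names); r <- length(model$y_names)
  wm <- array(NA_real_, c(g, g, p), dimnames = list(NULL, NULL, model$x_names))
  for (j in seq_len(p))
    wm[, , j] <- matrix(model$input_weights[, j], g, g, byrow = TRUE)
  U <- minmax_invert(model$output_weights, model$norm_y)
  om <- array(NA_real_, c(g, g, r), dimnames = list(NULL, NULL, model$y_names))
  for (j in seq_len(r))
    om[, , j] <- matrix(U[, j], g, g, byrow = TRUE)
  structure(list(top = top, weight_maps = wm, output_maps = om, grid = g),
            class = "cpann_maps")
}

#' @export
print.cpann_maps <- function(x, ...) {
  cat("CPANN map set: ", nrow(x$top), " objects on a ", x$grid, " x ",
      x$grid, " lattice; ", dim(x$weight_maps)[3], " weight plane(s), ",
      dim(x$output_maps)[3], " output plane(s)\n", sep = "")
  invisible(x)
}

#' Plot a CPANN map plane
#'
#' Renders one weight or output plane as a colour-coded lattice image, with
#' the objects of the top map overlaid.
#'
#' @param x a `cpann_maps` object.
#' @param plane name of a descriptor or response plane.
#' @param show_objects overlay object positions.
#' @param ... passed to [graphics::image()].
#' @export
plot.cpann_maps <- function(x, plane = dimnames(x$output_maps)[[3]][1],
                            show_objects = TRUE, ...) {
  m <- if (plane %in% dimnames(x$output_maps)[[3]]) x$output_maps[, , plane]
       else if (plane %in% dimnames(x$weight_maps)[[3]]) x$weight_maps[, , plane]
       else fd_stop("parameter", "no plane named '%s'", plane)
  graphics::image(seq_len(x$grid), seq_len(x$grid), t(m[x$grid:1, ]),
                  col = grDevices::hcl.colors(64, "RdYlBu", rev = TRUE),
                  xlab = "column", ylab = "row", main = plane, ...)
  if (show_objects)
    graphics::points(x$top$col, x$grid + 1 - x$top$row, pch = 21,
                     bg = "white")
  invisible(x)
}

#' Plot CPANN training diagnostics
#'
#' Quantization error per epoch.
#'
#' @param x a fitted `cpann`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.cpann <- function(x, ...) {
  graphics::plot(seq_along(x$qe), x$qe, type = "l", xlab = "epoch",
                 ylab = "quantization error", ...)
  invisible(x)
}
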