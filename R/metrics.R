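# Shared model-quality metrics and min-max normalization helpers.

#' Root mean squared error
#' @param obs,pred numeric vectors of equal length.
#' @return a number.
#' @export
rmse <- function(obs, pred) {
  fd_assert(length(obs) == length(pred), "dimension",
            "obs (%d) and pred (%d) differ in length", length(obs),
            length(pred))
  sqrt(mean((obs - pred)^2))
}

#' Squared-correlation Q2
#'
#' Squared Pearson correlation between observed and predicted values, the
#' package's primary Q^2 definition. Warns when the underlying correlation is
#' negative, since anti-correlated predictions give a deceptively high value
#' under this definition.
#'
#' @param obs,pred numeric vectors of equal length.
#' @return a number in [0, 1].
#' @export
q2_pearson <- function(obs, pred) {
  fd_assert(length(obs) == length(pred), "dimension",
            "obs (%d) and pred (%d) differ in length", length(obs),
            length(pred))
  fd_assert(stats::sd(obs) > 0, "metric", "observed values are constant")
  if (stats::sd(pred) == 0) return(0)
  r <- stats::cor(obs, pred)
  if (r < 0)
    warning("predictions are anti-correlated with observations (r = ",
            round(r, 3), "); squared-correlation Q2 is misleading here",
            call. = FALSE)
  r^2
}

#' PRESS-based external Q2
#'
#' `1 - sum((obs - pred)^2) / sum((obs - ref_mean)^2)`, with `ref_mean` the
#' training-set response mean; the second Q^2 definition reported throughout
#' the package.
#'
#' @param obs,pred numeric vectors of equal length.
#' @param ref_mean training-set response mean.
#' @return a number (at most 1, unbounded below).
#' @export
q2_press <- function(obs, pred, ref_mean) {
  fd_assert(length(obs) == length(pred), "dimension",
            "obs (%d) and pred (%d) differ in length", length(obs),
            length(pred))
  ss <- sum((obs - ref_mean)^2)
  fd_assert(ss > 0, "metric", "observed values are constant")
  1 - sum((obs - pred)^2) / ss
}

minmax_fit <- function(X) {
  X <- as.matrix(X)
  rng <- apply(X, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1     # constant column: mapped to 0, span kept harmless
  list(min = rng[1, ], span = span, names = colnames(X))
}

minmax_apply <- function(X, nm, clip = FALSE) {
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, nm$min), 2, nm$span, "/")
  if (clip) {
    out_of_hull <- Z < 0 | Z > 1
    if (any(out_of_hull)) {
      warning(sum(out_of_hull), " value(s) outside the training range were ",
              "clipped to [0, 1]", call. = FALSE)
      Z[Z < 0] <- 0
      Z[Z > 1] <- 1
    }
  }
  Z
}

minmax_invert <- function(Z, nm) {
  sweep(sweep(as.matrix(Z), 2, nm$span, "*"), 2, nm$min, "+")
}
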