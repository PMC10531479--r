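# SMILES-attribute optimal descriptor (DCW): a single descriptor formed as
# the sum of per-fragment "correlation weights" over the attributes of a
# compound's canonical SMILES, with the weights tuned by greedy Monte-Carlo
# hill climbing to maximize |Pearson r| against a training endpoint.

#' Extract SMILES attributes
#'
#' Order-1 attributes are the single tokens of the canonicalized SMILES
#' (multi-character atoms such as `Cl`, `Br` and bracket atoms are one token;
#' ring-bond digits are retained). Order-2 attributes are adjacent token
#' pairs, written in lexicographic order.
#'
#' @param smiles a single SMILES string.
#' @param order 1 or 2.
#' @param canonicalize canonicalize the SMILES first (default `TRUE`; the fit
#'   and predict paths always canonicalize so attributes do not depend on the
#'   input atom ordering).
#' @return named integer vector: attribute multiset with counts.
#' @examples
#' extract_attributes("CCO", order = 1, canonicalize = FALSE)  # C:2, O:1
#' @export
extract_attributes <- function(smiles, order = 2L, canonicalize = TRUE) {
  fd_assert(order %in% c(1L, 2L), "parameter", "order must be 1 or 2")
  if (canonicalize) smiles <- canonical_smiles(smiles)
  tk <- smiles_tokens(smiles)
  attrs <- if (order == 1L) {
    tk
  } else {
    if (length(tk) == 1L) tk else {
      a <- tk[-length(tk)]
      b <- tk[-1L]
      c(tk, paste(pmin(a, b), pmax(a, b), sep = "~"))
    }
  }
  tab <- table(attrs)
  stats::setNames(as.integer(tab), names(tab))
}

attribute_matrix <- function(smiles_vec, order, canonicalize = TRUE) {
  if (canonicalize) smiles_vec <- canonical_smiles(smiles_vec)
  sets <- lapply(smiles_vec, extract_attributes, order = order,
                 canonicalize = FALSE)
  all_attrs <- sort(unique(unlist(lapply(sets, names))))
  M <- matrix(0L, nrow = length(sets), ncol = length(all_attrs),
              dimnames = list(NULL, all_attrs))
  for (i in seq_along(sets))
    M[i, names(sets[[i]])] <- sets[[i]]
  M
}

#' Value of the DCW descriptor for an attribute multiset
#'
#' Sum over attributes of count x weight. Attributes that were below the
#' training-occurrence threshold (weight fixed at 0) and attributes never seen
#' in training contribute nothing; unknown attributes are counted in the
#' `"n_unknown"` attribute of the result.
#'
#' @param attributes named integer vector from
#'   \code{\link{extract_attributes}}.
#' @param model a fitted `dcw` model.
#' @return a number with attribute `n_unknown`.
#' @export
dcw_value <- function(attributes, model) {
  fd_assert(inherits(model, "dcw"), "state", "model is not a fitted dcw")
  known <- intersect(names(attributes), names(model$weights))
  unknown <- setdiff(names(attributes), names(model$weights))
  v <- sum(attributes[known] * model$weights[known])
  attr(v, "n_unknown") <- length(unknown)
  v
}

#' Fit a DCW optimal-descriptor model
#'
#' Attributes occurring in at least `threshold` training compounds are
#' "active"; their correlation weights start at 1 and are optimized by greedy
#' Monte-Carlo hill climbing: each move perturbs one randomly chosen active
#' weight by `+step` or `-step` and is kept iff the absolute Pearson
#' correlation between the resulting DCW values and the endpoint does not
#' decrease on the training set. One epoch is one pass of as many moves as
#' there are active attributes. Sub-threshold attributes keep weight 0. After
#' optimization an ordinary-least-squares calibration line mapping DCW to
#' endpoint units is fitted on the training set only.
#'
#' @param smiles character vector of training SMILES.
#' @param y numeric endpoint (same length).
#' @param order attribute order, 1 or 2 (default 2).
#' @param threshold minimum number of training compounds containing an
#'   attribute for it to be active (default 3).
#' @param epochs optimization passes (default 30).
#' @param step weight perturbation size (default 0.1).
#' @param seed integer seed; fixed seed gives identical weight maps.
#' @return an object of class `dcw`.
#' @export
dcw <- function(smiles, y, order = 2L, threshold = 3L, epochs = 30L,
                step = 0.1, seed = 1L) {
  fd_assert(length(smiles) == length(y), "dimension",
            "smiles (%d) and y (%d) differ in length", length(smiles),
            length(y))
  fd_assert(length(y) >= 10, "parameter",
            "at least 10 training compounds required (got %d)", length(y))
  fd_assert(stats::sd(y) > 0, "metric", "endpoint has no variance")
  fd_assert(threshold >= 1, "parameter", "threshold must be >= 1")

  M <- attribute_matrix(smiles, order)
  occurrence <- colSums(M > 0)
  active <- which(occurrence >= threshold)
  if (length(active) == 0)
    fd_stop("optimization",
            "no active attributes: all %d fall below the occurrence threshold %d",
            ncol(M), threshold)

  Ma <- M[, active, drop = FALSE]
  w <- stats::setNames(rep(1, length(active)), colnames(Ma))

  score <- function(d) if (stats::sd(d) == 0) 0 else abs(stats::cor(d, y))
  d_cur <- as.numeric(Ma %*% w)
  r_cur <- score(d_cur)
  r_trace <- r_cur

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  n_moves <- as.integer(epochs) * length(active)
  for (m in seq_len(n_moves)) {
    j <- sample.int(length(active), 1L)
    delta <- sample(c(-step, step), 1L)
    d_new <- d_cur + delta * Ma[, j]
    r_new <- score(d_new)
    if (r_new >= r_cur) {
      w[j] <- w[j] + delta
      d_cur <- d_new
      r_cur <- r_new
      r_trace <- c(r_trace, r_cur)
    }
  }

  cal <- stats::lm.fit(cbind(1, d_cur), y)
  weights_full <- stats::setNames(rep(0, ncol(M)), colnames(M))
  weights_full[names(w)] <- w

  structure(list(
    weights = weights_full, active = colnames(Ma),
    order = as.integer(order), threshold = as.integer(threshold),
    epochs = as.integer(epochs), step = step, seed = as.integer(seed),
    calibration = c(intercept = unname(cal$coefficients[1]),
                    slope = unname(cal$coefficients[2])),
    train_r = r_cur, r_trace = r_trace,
    train_dcw = d_cur, train_y = y), class = "dcw")
}

#' @export
print.dcw <- function(x, ...) {
  cat("DCW optimal descriptor (order ", x$order, ", threshold ", x$threshold,
      ", ", x$epochs, " epochs, step ", x$step, ")\n", sep = "")
  cat("  active attributes: ", length(x$active), " of ", length(x$weights),
      "\n", sep = "")
  cat("  training |r|: ", round(x$train_r, 4), "\n", sep = "")
  cat("  calibration: y = ", signif(x$calibration["intercept"], 5), " + ",
      signif(x$calibration["slope"], 5), " * DCW\n", sep = "")
  invisible(x)
}

#' @export
coef.dcw <- function(object, active_only = TRUE, ...) {
  if (active_only) object$weights[object$active] else object$weights
}

#' Predict with a DCW model
#'
#' Computes the raw DCW value of each molecule with the frozen weights and,
#' by default, maps it to endpoint units through the frozen training
#' calibration line (no leakage: nothing is refit).
#'
#' @param object a fitted `dcw`.
#' @param smiles character vector of SMILES.
#' @param type `"response"` (calibrated endpoint units) or `"dcw"` (raw
#'   descriptor value).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.dcw <- function(object, smiles, type = c("response", "dcw"), ...) {
  type <- match.arg(type)
  smiles <- canonical_smiles(smiles)
  vals <- vapply(smiles, function(s) {
    a <- extract_attributes(s, order = object$order, canonicalize = FALSE)
    as.numeric(dcw_value(a, object))
  }, numeric(1), USE.NAMES = FALSE)
  if (type == "dcw") vals else
    object$calibration["intercept"] + object$calibration["slope"] * vals
}

#' Serialize a DCW model to JSON
#'
#' @param model a fitted `dcw`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dcw <- function(model, path) {
  fd_assert(inherits(model, "dcw"), "parameter", "model is not a dcw")
  jsonlite::write_json(list(
    weights = as.list(model$weights), active = model$active,
    order = model$order, threshold = model$threshold, epochs = model$epochs,
    step = model$step, seed = model$seed,
    calibration = as.list(model$calibration), train_r = model$train_r),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
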