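# Local structural-alert screening for aquatic toxicity: a shipped SMARTS
# library (14 alerts written from the printed chemical names of the ToxAlerts
# aquatic-toxicity identifiers, with paired positive/negative control
# structures defining each pattern's contract) and substructure screening.

#' Load a structural-alert library
#'
#' With no arguments, the 14 built-in aquatic-toxicity alerts are loaded. A
#' user JSON file (same schema: `alert_id`, `name`, `smarts` array, optional
#' `note`) can extend or override the defaults; an entry whose `alert_id`
#' matches a built-in replaces it.
#'
#' @param path optional path to a user alert JSON file.
#' @param include_defaults include the built-in alerts (default `TRUE`).
#' @return an object of class `alert_library`.
#' @export
load_alert_library <- function(path = NULL, include_defaults = TRUE) {
  read_defs <- function(p) {
    defs <- jsonlite::read_json(p, simplifyVector = FALSE)
    fd_assert(length(defs) == 0 || all(vapply(defs, function(d)
      all(c("alert_id", "name", "smarts") %in% names(d)), logical(1))),
      "load", "alert file %s: every entry needs alert_id, name, smarts", p)
    ids <- vapply(defs, `[[`, character(1), "alert_id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup) > 0)
      fd_stop("load", "duplicate alert_id in %s: %s", p,
              paste(dup, collapse = ", "))
    stats::setNames(defs, ids)
  }
  defs <- list()
  if (isTRUE(include_defaults)) {
    default_path <- system.file("extdata", "aquatic_alerts.json",
                                package = "fdtox", mustWork = TRUE)
    defs <- read_defs(default_path)
  }
  if (!is.null(path)) {
    fd_assert(file.exists(path), "load", "alert file not found: %s", path)
    user <- read_defs(path)
    defs[names(user)] <- user
  }
  # every SMARTS must compile: probe each against a trivial molecule
  for (id in names(defs)) {
    for (pat in unlist(defs[[id]]$smarts)) {
      ok <- tryCatch({
        smarts_count("C", pat)
        TRUE
      }, error = function(e) FALSE)
      if (!ok)
        fd_stop("load", "alert %s: SMARTS does not compile: %s", id, pat)
    }
  }
  structure(list(alerts = defs), class = "alert_library")
}

#' @export
print.alert_library <- function(x, ...) {
  cat("Structural-alert library: ", length(x$alerts), " alert(s)\n", sep = "")
  for (a in x$alerts)
    cat("  ", a$alert_id, "  ", a$name, " (", length(unlist(a$smarts)),
        " pattern(s))\n", sep = "")
  invisible(x)
}

#' Write an alert library to JSON
#'
#' @param library an `alert_library`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_alert_library <- function(library, path) {
  fd_assert(inherits(library, "alert_library"), "parameter",
            "library must be an alert_library")
  jsonlite::write_json(unname(library$alerts), path, auto_unbox = TRUE)
  invisible(path)
}

#' Screen molecules against a structural-alert library
#'
#' Counts symmetry-deduplicated substructure matches of every alert pattern;
#' an alert with several depiction variants sums their (mutually exclusive)
#' counts. Screening is performed on canonical structures, so the result does
#' not depend on how the input SMILES was written.
#'
#' @param smiles character vector of SMILES (or an `fd_mols`).
#' @param library an `alert_library` (default: built-ins).
#' @param ids optional compound identifiers.
#' @return data frame of hits: `id`, `alert_id`, `name`, `count`
#'   (only rows with `count >= 1`).
#' @examples
#' \donttest{screen("CCO")   # TA659, aliphatic alcohol}
#' @export
screen <- function(smiles, library = load_alert_library(), ids = NULL) {
  if (inherits(smiles, "fd_mols")) {
    if (is.null(ids)) ids <- smiles$ids
    smiles <- smiles$smiles
  }
  fd_assert(inherits(library, "alert_library"), "parameter",
            "library must be an alert_library")
  if (is.null(ids)) ids <- paste0("FD", seq_along(smiles))
  if (length(library$alerts) == 0)
    return(data.frame(id = character(0), alert_id = character(0),
                      name = character(0), count = integer(0)))
  counts <- matrix(0L, nrow = length(smiles), ncol = length(library$alerts),
                   dimnames = list(NULL,
                                   vapply(library$alerts, `[[`, character(1),
                                          "alert_id")))
  for (a in library$alerts) {
    total <- integer(length(smiles))
    for (pat in unlist(a$smarts)) total <- total + smarts_count(smiles, pat)
    counts[, a$alert_id] <- total
  }
  hits <- which(counts >= 1L, arr.ind = TRUE)
  if (nrow(hits) == 0)
    return(data.frame(id = character(0), alert_id = character(0),
                      name = character(0), count = integer(0)))
  nm <- vapply(library$alerts, `[[`, character(1), "name")
  out <- data.frame(
    id = ids[hits[, 1]],
    alert_id = colnames(counts)[hits[, 2]],
    name = unname(nm[colnames(counts)[hits[, 2]]]),
    count = counts[hits],
    stringsAsFactors = FALSE)
  out[order(match(out$id, ids), out$alert_id), , drop = FALSE]
}

#' Alert control structures
#'
#' The 28 positive/negative control SMILES shipped with the package; each
#' alert's paired controls define the contract of its SMARTS patterns.
#'
#' @return data frame with columns `alert_id`, `role`, `smiles`, `name`.
#' @export
alert_controls <- function() {
  utils::read.csv(system.file("extdata", "alert_controls.csv",
                              package = "fdtox", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Per-compound alert screening report
#'
#' Joins predicted binding scores with alert hits: one row per compound with
#' its predicted score, the alerts found (ids and counts), a group key (the
#' sorted set of shared alerts, the analogue of grouping compounds by common
#' alerts), and a review flag for compounds whose predicted score is at or
#' above `threshold` yet carry no alert (high predicted binding with no known
#' toxicophore warrants manual inspection).
#'
#' @param ids compound identifiers.
#' @param predicted_scores numeric vector of predicted average binding scores,
#'   aligned with `ids`.
#' @param hits data frame from \code{\link{screen}}.
#' @param threshold concern threshold on the predicted score (default 5000).
#' @return data frame, one row per compound: `id`, `score`, `alerts`,
#'   `n_alerts`, `group`, `review`.
#' @export
screening_report <- function(ids, predicted_scores, hits, threshold = 5000) {
  fd_assert(length(ids) == length(predicted_scores), "join",
            "ids (%d) and predicted_scores (%d) differ in length",
            length(ids), length(predicted_scores))
  fd_assert(!anyDuplicated(ids), "join", "duplicate compound ids")
  extra <- setdiff(hits$id, ids)
  if (length(extra) > 0)
    fd_stop("join", "alert hits reference unknown id(s): %s",
            paste(utils::head(extra, 5), collapse = ", "))
  alert_str <- vapply(ids, function(i) {
    h <- hits[hits$id == i, , drop = FALSE]
    if (nrow(h) == 0) "" else
      paste(sprintf("%s(%d)", h$alert_id, h$count), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  n_alerts <- vapply(ids, function(i) sum(hits$id == i), integer(1),
                     USE.NAMES = FALSE)
  group_key <- vapply(ids, function(i) {
    h <- hits[hits$id == i, , drop = FALSE]
    if (nrow(h) == 0) "none" else paste(sort(h$alert_id), collapse = "+")
  }, character(1), USE.NAMES = FALSE)
  # number groups by decreasing mean predicted score (alert-free last)
  grp_means <- tapply(predicted_scores, group_key, mean)
  keys <- names(sort(grp_means, decreasing = TRUE))
  keys <- c(setdiff(keys, "none"), if ("none" %in% keys) "none")
  group_no <- match(group_key, keys)
  data.frame(id = ids, score = predicted_scores, alerts = alert_str,
             n_alerts = n_alerts, group_key = group_key, group = group_no,
             review = predicted_scores >= threshold & n_alerts == 0,
             stringsAsFactors = FALSE)
}
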