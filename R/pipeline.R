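# End-to-end orchestration: data -> descriptors -> DCW -> model registry ->
# applicability domain -> alert screening -> ranked prioritization table,
# with a reproducible run manifest.

#' Rank compounds by predicted binding score
#'
#' Descending predicted average binding score; ties broken by compound id
#' (stable). Compounds outside the applicability domain are retained and
#' flagged, never dropped.
#'
#' @param predictions data frame with columns `id` and `score`.
#' @param report screening report from \code{\link{screening_report}}.
#' @param ad_flags optional data frame with columns `id` and
#'   `structural_outlier` (e.g. the `williams` table).
#' @return prioritization data frame sorted by decreasing score.
#' @export
rank_compounds <- function(predictions, report, ad_flags = NULL) {
  fd_assert(all(c("id", "score") %in% names(predictions)), "parameter",
            "predictions needs columns id and score")
  fd_assert(!anyDuplicated(predictions$id), "join", "duplicate compound ids")
  fd_assert(setequal(predictions$id, report$id), "join",
            "predictions and alert report cover different compounds")
  out <- merge(predictions[, c("id", "score")],
               report[, c("id", "alerts", "n_alerts", "group", "review")],
               by = "id", sort = FALSE)
  if (!is.null(ad_flags)) {
    fd_assert(all(c("id", "structural_outlier") %in% names(ad_flags)),
              "parameter", "ad_flags needs columns id and structural_outlier")
    out <- merge(out, ad_flags[, c("id", "structural_outlier")], by = "id",
                 sort = FALSE)
    names(out)[names(out) == "structural_outlier"] <- "outside_ad"
  } else {
    out$outside_ad <- NA
  }
  out[order(-out$score, out$id), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the compound table, computes descriptors, fits the
#' endpoint-specific DCW models and the six-family model registry, derives the
#' Williams applicability-domain table for the two-descriptor regression of
#' the average binding score, exports the CPANN map set, screens all
#' structures against the alert library, and writes a ranked prioritization
#' table. All artifacts are written under `out_dir` together with a JSON run
#' manifest (seeds, file digests, package version).
#'
#' @param config an `fd_generator_config`, a path to a YAML file with a
#'   `generator` section of \code{\link{generator_config}} arguments, or
#'   `NULL` for the default configuration.
#' @param data_file optional CSV of a real compound table (see
#'   \code{\link{read_dataset}}); when given, generation is skipped and the
#'   recorded split is honored verbatim.
#' @param out_dir output directory (created if needed).
#' @param registry_params list with optional `dcw` and `cpann` sub-lists
#'   passed to \code{\link{build_registry}}.
#' @param threshold concern threshold for the alert report (default 5000).
#' @return (invisibly) a list with the dataset, registry, williams table,
#'   maps, alert report, prioritization table, and the manifest.
#' @export
run_pipeline <- function(config = NULL, data_file = NULL,
                         out_dir = tempfile("fdtox_run_"),
                         registry_params = list(), threshold = 5000) {
  if (is.character(config)) {
    fd_assert(file.exists(config), "config", "config file not found: %s",
              config)
    yml <- yaml::read_yaml(config)
    gen_args <- if (!is.null(yml$generator)) yml$generator else list()
    if (!is.null(yml$data_file) && is.null(data_file))
      data_file <- yml$data_file
    if (!is.null(yml$threshold)) threshold <- yml$threshold
    config <- do.call(generator_config, gen_args)
  }
  if (is.null(config)) config <- generator_config()

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  dataset <- if (!is.null(data_file)) read_dataset(data_file)
             else generate_dataset(config)
  fd_assert(!is.null(dataset$descriptors), "data",
            "descriptor table unavailable")

  write_dataset(dataset, file.path(out_dir, "compounds.csv"))

  registry <- build_registry(dataset,
                             dcw_params = registry_params$dcw %||% list(),
                             cpann_params = registry_params$cpann %||% list())
  reg_summary <- summary(registry)
  utils::write.csv(reg_summary, file.path(out_dir, "registry_summary.csv"),
                   row.names = FALSE)
  write_dcw(registry$dcw_models$AvgBScore,
            file.path(out_dir, "dcw_avgbscore.json"))

  # applicability domain of the two-descriptor regression, average response
  X2 <- as.matrix(dataset$descriptors[, c("QPpolrz", "TD")])
  reg1 <- registry$entries$regression_1$AvgBScore$model
  wil <- williams(reg1, X2, dataset$responses$AvgBScore,
                  dataset$compounds$split, ids = dataset$compounds$id)
  utils::write.csv(wil$table, file.path(out_dir, "williams_regression1.csv"),
                   row.names = FALSE)

  # CPANN maps from the ALL model
  all_net <- registry$entries$ALL_CPANN[[1]]$model
  Dall <- cbind(as.matrix(dataset$descriptors),
                DCW = predict(registry$dcw_models$AvgBScore,
                              dataset$compounds$smiles, type = "dcw"))
  maps <- cpann_maps(all_net, Dall[, all_net$x_names, drop = FALSE],
                     ids = dataset$compounds$id)
  utils::write.csv(maps$top, file.path(out_dir, "top_map.csv"),
                   row.names = FALSE)

  # alert screening against predicted average binding score (regression 1)
  hits <- screen(dataset$compounds$smiles, ids = dataset$compounds$id)
  pred_avg <- predict(reg1, X2)
  report <- screening_report(dataset$compounds$id, pred_avg, hits,
                             threshold = threshold)
  utils::write.csv(report, file.path(out_dir, "alert_report.csv"),
                   row.names = FALSE)

  ranking <- rank_compounds(
    data.frame(id = dataset$compounds$id, score = pred_avg),
    report,
    ad_flags = wil$table)
  utils::write.csv(ranking, file.path(out_dir, "prioritization.csv"),
                   row.names = FALSE)

  outputs <- c("compounds.csv", "registry_summary.csv", "dcw_avgbscore.json",
               "williams_regression1.csv", "top_map.csv", "alert_report.csv",
               "prioritization.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("fdtox")),
    seed = if (!is.null(dataset$config)) dataset$config$seed else NA,
    data_file = if (is.null(data_file)) "synthetic" else data_file,
    n_compounds = nrow(dataset$compounds),
    outputs = as.list(stats::setNames(
      as.character(tools::md5sum(file.path(out_dir, outputs))), outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(dataset = dataset, registry = registry, williams = wil,
                 maps = maps, alert_report = report, ranking = ranking,
                 manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
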