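# Pipeline configuration: one YAML file drives simulation, feature
# extraction, curation, balancing, and evaluation. Every default equals
# the pipeline's published setting where one exists (trim 20 s / 10 s,
# median kernel 9, 20% event threshold, |r| >= 0.80, 10 RFE features,
# 100 trees, SMOTE k = 5, 5 folds).

#' Default pipeline configuration
#'
#' @param seed master seed fanned out to every stochastic stage.
#' @return nested list of class `pipeline_config` with sections
#'   `simulate`, `preprocess`, `events`, `features`, `curation`, `smote`,
#'   `models`, and `evaluation`.
#' @export
pipeline_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulate = list(n_per_class = 10, walk_duration = 60,
                    severity_gradient = 1, noise_sd = 8, n_walks = 1,
                    task = "binary"),
    preprocess = list(head_trim = 20, tail_trim = 10, median_kernel = 9,
                      normalize = TRUE),
    events = list(threshold_frac = 0.2),
    features = list(window = 10, reference_speed = 1.2),
    curation = list(r_threshold = 0.80, n_keep = 10, n_trees = 100),
    smote = list(k_neighbors = 5),
    models = list(run = c("KNN", "DT", "RF", "GB", "XGB"), tune = FALSE),
    evaluation = list(n_folds = 5, split_unit = "subject_grouped",
                      inner_folds = 5)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are a validation error; missing keys fall back to the
#' defaults of [pipeline_config()].
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop_crisp("crisp_validation_error", "config file not found: %s", path)
  user <- yaml::read_yaml(path)
  base <- pipeline_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop_crisp("crisp_validation_error",
               "unknown config section(s): %s", paste(bad, collapse = ", "))
  for (sec in names(user)) {
    if (!is.list(base[[sec]])) { base[[sec]] <- user[[sec]]; next }
    badk <- setdiff(names(user[[sec]]), names(base[[sec]]))
    if (length(badk))
      stop_crisp("crisp_validation_error",
                 "unknown key(s) in '%s': %s", sec,
                 paste(badk, collapse = ", "))
    base[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  base
}

# Manifest naming the config hash and seed that produced a run's artifacts.
write_manifest <- function(config, out_dir, extra = list()) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(unclass(config)), tmp)
  manifest <- c(list(config_hash = unname(tools::md5sum(tmp)),
                     seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("crispgait")),
                     timestamp = format(Sys.time(), tz = "UTC")), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
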