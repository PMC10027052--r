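# On-disk containers. Datasets are stored as R-native serialized lists with
# a fixed logical schema (dfbf array + ground truth + config + watermark +
# schema version); results tables are CSV with full-precision floats and
# Booleans as 0/1.

SCHEMA_VERSION <- "1.0"

#' Write a dataset container
#'
#' Serializes a synthetic dataset (or an imported dF/F tensor wrapped in
#' the same schema) to disk. Synthetic files always carry the watermark;
#' imported physiology files must not.
#'
#' @param dataset A `tc_dataset`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "tc_dataset"))
  obj <- list(schema_version = SCHEMA_VERSION,
              watermark = dataset$watermark,
              frame_rate_hz = dataset$config$frame_rate,
              dfbf = dataset$dfbf,
              ground_truth = dataset$truth,
              config = unclass(dataset$config))
  saveRDS(obj, path)
  invisible(path)
}

#' Read a dataset container
#'
#' @param path File written by [write_dataset()].
#' @return A `tc_dataset`.
#' @export
read_dataset <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$schema_version) || is.null(obj$dfbf))
    stop("malformed dataset container: ", path)
  if (is.null(obj$watermark))
    stop("container lacks the synthetic-data watermark: ", path)
  cfg <- obj$config
  class(cfg) <- "tc_config"
  structure(list(dfbf = obj$dfbf, truth = obj$ground_truth, config = cfg,
                 watermark = obj$watermark),
            class = "tc_dataset")
}

#' Wrap an arbitrary dF/F tensor for the pipeline
#'
#' Builds a minimal unlabeled `tc_dataset`-like object around an imported
#' cells x trials x frames dF/F array so the detectors and the results
#' table can be used on real physiology data.
#'
#' @param dfbf 3-D dF/F array.
#' @param frame_rate Hz.
#' @param stim_window Length-2 frames used by the detectors.
#' @return A `tc_dataset` with NA truth labels and no watermark semantics
#'   (the watermark field is set to `NA`).
#' @export
import_dfbf <- function(dfbf, frame_rate = 14.5, stim_window) {
  check_dfbf(dfbf)
  d <- dim(dfbf)
  cfg <- dataset_config(n_cells = d[1], n_trials = d[2], n_frames = d[3],
                        frame_rate = frame_rate,
                        start_frame = stim_window[1],
                        end_frame = stim_window[2],
                        stim_window = stim_window,
                        time_cell_percent = 0, noise_type = "none",
                        noise_percent = 0)
  truth <- list(is_time_cell = rep(NA, d[1]))
  structure(list(dfbf = dfbf, truth = truth, config = cfg,
                 watermark = NA_character_),
            class = "tc_dataset")
}

#' Write a results table to CSV
#'
#' Fixed header, one row per cell, Booleans as 0/1, floats at full
#' precision.
#'
#' @param results Table from [score_dataset()] or [run_suite()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results
  for (cn in names(out))
    if (is.logical(out[[cn]])) out[[cn]] <- as.integer(out[[cn]])
  write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path CSV path.
#' @return data.frame with prediction columns restored to logical.
#' @export
read_results <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  for (cn in grep("^pred_", names(out), value = TRUE))
    out[[cn]] <- as.logical(as.integer(out[[cn]]))
  if ("truth" %in% names(out) && !all(is.na(out$truth)))
    out$truth <- as.logical(as.integer(out$truth))
  out
}

#' Write a dataset configuration as YAML
#'
#' Keys match the [dataset_config()] argument names exactly.
#'
#' @param config A `tc_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML configs")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a YAML dataset configuration
#'
#' @param path YAML path with [dataset_config()] keys.
#' @return A validated `tc_config`.
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML configs")
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  do.call(dataset_config, vals)
}
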