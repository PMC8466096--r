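#' Read and validate a pipeline configuration file
#'
#' The configuration is a YAML (or JSON) file with two blocks: `simulate`
#' (arguments of [sim_config()]; alternatively `input: <directory>` pointing
#' at a dataset written by [write_dataset()]) and `pipeline` (arguments of
#' [run_pipeline()] other than the dataset). Unknown keys are errors, so a
#' mistyped threshold cannot silently fall back to a default.
#'
#' @param path path to the configuration file.
#' @return validated list with elements `simulate` (or `input`) and
#'   `pipeline`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_input("config file '%s' not found", path)
  cfg <- yaml::read_yaml(path)
  allowed_top <- c("simulate", "input", "pipeline")
  unknown <- setdiff(names(cfg), allowed_top)
  if (length(unknown))
    stop_input("unknown configuration key(s): %s", paste(unknown, collapse = ", "))
  if (is.null(cfg$simulate) && is.null(cfg$input))
    stop_input("configuration needs either a 'simulate' block or an 'input' directory")

  if (!is.null(cfg$simulate)) {
    allowed_sim <- names(formals(sim_config))
    unknown <- setdiff(names(cfg$simulate), allowed_sim)
    if (length(unknown))
      stop_input("unknown simulate key(s): %s", paste(unknown, collapse = ", "))
  }
  allowed_pipe <- setdiff(names(formals(run_pipeline)), c("dataset", "de_table"))
  if (!is.null(cfg$pipeline)) {
    unknown <- setdiff(names(cfg$pipeline), c(allowed_pipe, "de_table_file"))
    if (length(unknown))
      stop_input("unknown pipeline key(s): %s", paste(unknown, collapse = ", "))
  }
  cfg
}

#' Run the pipeline from a configuration file
#'
#' Resolves the dataset (simulating it or reading it from disk), runs
#' [run_pipeline()] with the configured thresholds, and optionally writes all
#' stage outputs.
#'
#' @param config path to a configuration file or a list from
#'   [read_pipeline_config()].
#' @param out_dir optional output directory (overrides nothing else).
#' @param seed optional seed overriding the one in the `simulate` block.
#' @return a `twinmeth_run` object.
#' @export
run_from_config <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!is.null(config$simulate)) {
    args <- config$simulate
    if (!is.null(seed)) args$seed <- seed
    dataset <- simulate_dataset(do.call(sim_config, args))
  } else {
    dataset <- read_dataset(config$input)
  }
  pipe_args <- config$pipeline
  if (!is.null(pipe_args$de_table_file)) {
    pipe_args$de_table <- utils::read.delim(pipe_args$de_table_file,
                                            stringsAsFactors = FALSE)
    pipe_args$de_table_file <- NULL
  }
  do.call(run_pipeline, c(list(dataset = dataset, out_dir = out_dir),
                          pipe_args))
}
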