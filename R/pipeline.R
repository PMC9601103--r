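#' @title Pipeline configuration and orchestration
#'
#' @description
#' A run configuration names the input tables, the detection threshold and
#' e-value cutoffs, and the output directory; [run_pipeline()] executes
#' the stages in order — module detection, suite screens, the
#' nitrogen-fixation screen, then matrix assembly — writing one TSV per
#' stage plus the assembled matrix. Precedence is CLI/`overrides` over
#' config file over defaults, and the effective configuration is written
#' beside the outputs for provenance. Outputs are written atomically
#' (temp file, then rename) and are byte-reproducible from
#' (inputs, config, seed).
#'
#' @name cli_config
NULL

config_defaults <- function() {
  list(
    modules = NULL, functions = NULL, bins = NULL, metadata = NULL,
    suites = NULL, groups = NULL,
    threshold = 2 / 3, count_mode = "steps",
    evalue_thresholds = list(),
    nif_e_max = 1e-100, nif_require_same_contig = FALSE,
    use_function_text_ec = FALSE,
    out_dir = ".", seed = 1L, log_level = "info")
}

#' Load and validate a run configuration
#'
#' @param path optional YAML config file; keys as in the defaults (see
#'   Details). Unknown keys are an error listing the valid keys.
#' @param overrides named list applied on top of the file values
#'   (CLI-flag precedence: overrides > file > defaults).
#' @details Valid keys: `modules`, `functions`, `bins`, `metadata`,
#'   `suites`, `groups` (input paths); `threshold` (fraction in (0, 1],
#'   default 2/3); `count_mode` (`"steps"`/`"genes"`); `evalue_thresholds`
#'   (map source -> max e-value); `nif_e_max`, `nif_require_same_contig`;
#'   `use_function_text_ec`; `out_dir`; `seed`; `log_level`.
#' @return a validated `run_config` list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    file_cfg <- yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           "; valid keys: ", paste(names(cfg), collapse = ", "),
           call. = FALSE)
    cfg[names(file_cfg)] <- file_cfg
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys: ", paste(names(cfg), collapse = ", "), call. = FALSE)
  cfg[names(overrides)] <- overrides

  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0 || cfg$threshold > 1)
    stop("threshold must be a fraction in (0, 1], got ", cfg$threshold,
         call. = FALSE)
  if (!cfg$count_mode %in% c("steps", "genes"))
    stop("count_mode must be 'steps' or 'genes'", call. = FALSE)
  for (key in c("modules", "functions", "bins", "metadata", "suites", "groups")) {
    p <- cfg[[key]]
    if (!is.null(p) && !file.exists(p))
      stop("config path for '", key, "' does not exist: ", p, call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message("[magmetab] ", ...)
}

write_tsv_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  file.rename(tmp, path)
  path
}

#' Run the full detection pipeline
#'
#' Stages, in order: read inputs (annotation store), score modules
#' (completeness engine), screen gene suites, run the nitrogen-fixation
#' screen, assemble and write the Boolean metabolism matrix. Any stage
#' failure aborts with an error naming the stage.
#'
#' @param config a `run_config` from [load_config()]; `modules`,
#'   `functions` and `bins` are required, `metadata`, `suites` and
#'   `groups` optional.
#' @return invisibly, a named list of output file paths
#'   (`completeness`, `suites` if run, `nif`, `matrix`, `config`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (key in c("modules", "functions", "bins"))
    if (is.null(config[[key]]))
      stop("config key '", key, "' is required by run_pipeline", call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()

  mags <- stage("annotation_store",
                read_annotations(config$functions, config$bins, config$metadata))
  mags <- mags[names(mags) != UNBINNED_MAG]
  modules <- stage("kegg_grammar", read_kegg_modules(config$modules))
  pipeline_log(config, "read ", length(mags), " MAG(s), ",
               length(modules), " module(s)")

  evth <- config$evalue_thresholds
  if (!length(evth)) evth <- NULL
  comp <- stage("completeness_engine",
                score_all(mags, modules, threshold = config$threshold,
                          count_mode = config$count_mode,
                          evalue_thresholds = evth))
  out$completeness <- write_tsv_atomic(comp, file.path(config$out_dir,
                                                       "completeness.tsv"))

  suite_res <- NULL
  if (!is.null(config$suites)) {
    suites <- stage("gene_suites", load_suites(config$suites))
    suite_res <- stage("gene_suites",
                       screen_suites(suites, mags,
                                     use_function_text_ec = config$use_function_text_ec))
    out$suites <- write_tsv_atomic(suite_res, file.path(config$out_dir,
                                                        "suite_results.tsv"))
  }

  nif_cfg <- nif_screen_config(e_max = config$nif_e_max,
                               require_same_contig = config$nif_require_same_contig)
  nif_res <- stage("nif_screen", screen_nif_all(mags, nif_cfg))
  out$nif <- write_tsv_atomic(nif_res, file.path(config$out_dir,
                                                 "nif_report.tsv"))

  groups <- NULL
  if (!is.null(config$groups))
    groups <- read_tsv_checked(config$groups, c("feature_name", "benefit_group"),
                               "groups")
  m <- stage("heatmap_report",
             build_matrix(completeness = comp, suites = suite_res,
                          nif = nif_res, metadata = mags_metadata(mags),
                          groups = groups))
  matrix_path <- file.path(config$out_dir, "matrix.tsv")
  tmp <- paste0(matrix_path, ".tmp")
  write_matrix(m, tmp, format = "tsv")
  file.rename(tmp, matrix_path)
  out$matrix <- matrix_path

  cfg_path <- file.path(config$out_dir, "effective_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  out$config <- cfg_path
  pipeline_log(config, "wrote ", length(out), " output file(s) to ",
               config$out_dir)
  invisible(out)
}
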