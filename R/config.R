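#' Run configuration
#'
#' Central container for the pipeline's fixed analysis parameters. Defaults
#' are the study's operating point: 2 x 36 bp paired reads with at most two
#' mismatches per end, 200-300 bp inserts, a 10 nt dot-plot word, BAC-overlap
#' assembly thresholds of >= 99.99% identity over >= 30 kb (relaxed: 99.85%
#' over 20 kb), 1000 bootstrap replicates, and a cattle/sheep calibration
#' split of 19.6 Mya. All values are overridable, here or in a YAML file.
#'
#' @param seed integer seed controlling every stochastic stage.
#' @param read_length read length in bp.
#' @param max_mismatches maximum substitutions allowed per aligned mate.
#' @param insert_min,insert_max fragment (insert) length bounds in bp.
#' @param dotplot_word exact-match word size for dot-plots, in bp.
#' @param assembly_min_identity,assembly_min_overlap stringent overlap
#'   thresholds (fraction identity, bp).
#' @param relaxed_min_identity,relaxed_min_overlap relaxed overlap thresholds.
#' @param active_min_aa minimum predicted peptide length (aa) for an active
#'   call.
#' @param active_min_fraction minimum predicted peptide length as a fraction
#'   of the reference peptide.
#' @param bootstrap_reps bootstrap replicate count for tree support.
#' @param calibration_time calibration split time in Mya.
#' @return a validated list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       read_length = 36L,
                       max_mismatches = 2L,
                       insert_min = 200L,
                       insert_max = 300L,
                       dotplot_word = 10L,
                       assembly_min_identity = 0.9999,
                       assembly_min_overlap = 30000L,
                       relaxed_min_identity = 0.9985,
                       relaxed_min_overlap = 20000L,
                       active_min_aa = 200L,
                       active_min_fraction = 0.40,
                       bootstrap_reps = 1000L,
                       calibration_time = 19.6) {
  cfg <- list(
    seed = as.integer(seed),
    read_length = as.integer(read_length),
    max_mismatches = as.integer(max_mismatches),
    insert_min = as.integer(insert_min),
    insert_max = as.integer(insert_max),
    dotplot_word = as.integer(dotplot_word),
    assembly_min_identity = as.numeric(assembly_min_identity),
    assembly_min_overlap = as.integer(assembly_min_overlap),
    relaxed_min_identity = as.numeric(relaxed_min_identity),
    relaxed_min_overlap = as.integer(relaxed_min_overlap),
    active_min_aa = as.integer(active_min_aa),
    active_min_fraction = as.numeric(active_min_fraction),
    bootstrap_reps = as.integer(bootstrap_reps),
    calibration_time = as.numeric(calibration_time)
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  counts <- c("read_length", "max_mismatches", "insert_min", "insert_max",
              "dotplot_word", "assembly_min_overlap", "relaxed_min_overlap",
              "active_min_aa", "bootstrap_reps")
  for (f in counts) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0L)
      stop("run_config: '", f, "' must be a non-negative count", call. = FALSE)
  }
  fracs <- c("assembly_min_identity", "relaxed_min_identity",
             "active_min_fraction")
  for (f in fracs) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0 || cfg[[f]] > 1)
      stop("run_config: '", f, "' must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$insert_min > cfg$insert_max)
    stop("run_config: insert_min must be <= insert_max", call. = FALSE)
  if (cfg$read_length > cfg$insert_min)
    stop("run_config: read_length must be <= insert_min", call. = FALSE)
  if (cfg$calibration_time <= 0)
    stop("run_config: calibration_time must be positive", call. = FALSE)
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' Unknown keys in the file are rejected; missing keys take their defaults.
#'
#' @param path file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param cfg a `run_config` object.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
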