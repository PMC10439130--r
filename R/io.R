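#' Read and write subject-level event-history tables
#'
#' Subject tables are plain CSV with columns `id`, `G`, `entry`, `C`,
#' `T`, `delta`, `W`, `t_unexposed`, `t_exposed`; a never-switcher has
#' an empty `W` field (not a sentinel number).
#'
#' @param data subject data frame as produced by [simulate_trial()].
#' @param path file path.
#' @return `write_subjects()` returns `path` invisibly;
#'   `read_subjects()` returns the validated subject data frame.
#' @export
write_subjects <- function(data, path) {
  cols <- c("id", "G", "entry", "C", "T", "delta", "W",
            "t_unexposed", "t_exposed")
  stopifnot(all(cols %in% names(data)))
  utils::write.csv(data[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  d <- utils::read.csv(path, na.strings = "")
  cols <- c("id", "G", "entry", "C", "T", "delta", "W",
            "t_unexposed", "t_exposed")
  missing <- setdiff(cols, names(d))
  if (length(missing))
    stop("subject table is missing columns: ", paste(missing, collapse = ", "))
  d$G <- as.integer(d$G)
  d$delta <- as.integer(d$delta)
  if (!all(d$delta %in% 0:2)) stop("delta must be 0, 1 or 2")
  if (!all(d$G %in% 0:1)) stop("G must be 0 or 1")
  if (any(d$T > d$C + 1e-8)) stop("observed time exceeds censoring time")
  d[, cols]
}

#' Read and write scenario configurations as YAML
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns a [scenario_config()].
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(scenario_config, x)
}
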