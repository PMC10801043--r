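# Plain-text configuration files for the generator.

#' Read a cohort configuration from a key/value file
#'
#' Parses a plain-text YAML key/value file into a [cohort_config()].
#' Only keys present in the file override the defaults; tabular fields
#' (`displacement_sigma`, `encoding_duration`, `recall_duration`,
#' `questionnaire_targets`) are given as lists of column vectors.
#'
#' @param path path to the configuration file.
#' @param seed optional integer overriding the file's (or default) seed,
#'   mirroring a command-line `--seed` flag.
#' @return a [cohort_config()].
#' @export
read_cohort_config <- function(path, seed = NULL) {
  if (!file.exists(path)) {
    input_error(sprintf("Config file not found: '%s'.", path))
  }
  raw <- yaml::read_yaml(path)
  tabular <- c("displacement_sigma", "encoding_duration", "recall_duration",
               "questionnaire_targets")
  for (key in intersect(tabular, names(raw))) {
    raw[[key]] <- as_tibble(raw[[key]])
  }
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s.",
                  paste(unknown, collapse = ", ")),
          class = "navassess_config_error")
  }
  cfg <- do.call(cohort_config, raw)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}
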