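# Run configuration: defaults reproduce the method's published settings
# (flank 20 / window 41, DF 10, C 1000, gamma 0.0038, smoothing flanks
# 12/4/15/8), overridable from a YAML file and CLI flags with precedence
# flags > file > defaults.

#' Default run configuration
#'
#' @return Nested list with components `seed`, `flank`, `features`
#'   (channels, df), `svm` (C, gamma), `postprocess` (own,
#'   morfpred_plus, morfchibi, combined smoothing flanks; PROMIS-style
#'   tracks default to no smoothing) and `sim` ([sim_config()] fields).
#' @export
default_run_config <- function() {
  list(seed = 1L,
       flank = 20L,
       features = list(channels = "HSEa_up", df = 10L),
       svm = list(C = 1000, gamma = 0.0038),
       postprocess = list(own = 12L, morfpred_plus = 4L, morfchibi = 15L,
                          combined = 8L),
       sim = list(n_sequences = 50L, length_range = c(60L, 600L),
                  morf_length_range = c(5L, 25L),
                  terminal_placement_prob = 0.3,
                  signal_channel = "HSEa_up",
                  background_mean = 10, background_sd = 2,
                  effect_size = 2, smoothing_halfwidth = 2L))
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  utils::modifyList(base, override)
}

#' Load a run configuration
#'
#' Reads a YAML config file (if given) over the defaults, then applies
#' overrides.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional nested list applied last.
#' @return The effective configuration list.
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      morf_stop("trimorf_validation_error", "config file not found: %s",
                path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  if (cfg$flank < 1L || cfg$features$df < 1L ||
      cfg$svm$C <= 0 || cfg$svm$gamma <= 0)
    morf_stop("trimorf_validation_error", "invalid configuration values")
  cfg
}

#' Write the effective configuration as YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
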