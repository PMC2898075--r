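## Pipeline configuration: every threshold of the comparison method with its
## published default, serializable as a flat YAML key-value file.

.config_defaults <- list(
  fragment_length    = "auto",  # bp, or "auto" for peak-pair estimation
  nucleosome_length  = 147,     # bp, mono-nucleosome footprint
  kernel_sd          = 25,      # bp, score-track Gaussian sd
  kernel_halfwidth   = 50,      # bp, kernel truncation
  low_score_quantile = 0.10,    # fraction of raw peaks discarded
  min_spacing        = 100,     # bp, peak suppression distance
  promoter_window    = 1000,    # bp, promoter extent for ordinal assignment
  max_pair_distance  = 100,     # bp, mutual-nearest pairing radius
  min_shift          = 15,      # bp, shift effect-size floor
  alpha              = 0.05,    # shift t-test threshold
  read_window        = 30,      # bp, fragment centers entering the t-test
  min_test_reads     = 3,       # per-strain minimum centers for the t-test
  shift_test         = "welch", # "welch" or "student"
  min_fold           = 2.0,     # occupancy / loss-gain fold threshold
  min_reads          = 8,       # loss-gain supporting-read floor
  occ_window         = 30,      # bp, occupancy averaging half-window
  tol_general        = 30,      # bp, strand-split position tolerance
  tol_shift          = 10,      # bp, strand-split tolerance for shifts
  fuzziness_window   = 20,      # bp, fuzziness distance threshold
  min_delta          = 5        # percentage points, fuzziness comparison
)

#' Pipeline configuration
#'
#' Collects every tunable threshold of the comparison pipeline with its
#' published default. Unknown names are errors, protecting against silent
#' threshold typos. The object round-trips losslessly through
#' \code{\link{writePipelineConfig}} / \code{\link{readPipelineConfig}}.
#'
#' @param ... name = value overrides of the defaults listed above.
#' @return named list of class \code{PipelineConfig}.
#' @examples
#' cfg <- pipelineConfig(min_shift = 20)
#' cfg$min_shift
#' @export
pipelineConfig <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- .config_defaults
  cfg[names(over)] <- over
  validateConfig(structure(cfg, class = c("PipelineConfig", "list")))
}

validateConfig <- function(cfg) {
  num <- c("nucleosome_length", "kernel_sd", "kernel_halfwidth",
           "min_spacing", "promoter_window", "max_pair_distance",
           "min_shift", "alpha", "read_window", "min_test_reads",
           "min_fold", "min_reads", "occ_window", "tol_general",
           "tol_shift", "fuzziness_window", "min_delta")
  for (k in num)
    if (!is.numeric(cfg[[k]]) || cfg[[k]] <= 0)
      stop("config '", k, "' must be a positive number")
  if (cfg$low_score_quantile < 0 || cfg$low_score_quantile > 1)
    stop("low_score_quantile must be in [0, 1]")
  if (cfg$alpha > 1) stop("alpha must be in (0, 1]")
  if (!identical(cfg$fragment_length, "auto") &&
      (!is.numeric(cfg$fragment_length) || cfg$fragment_length < 1))
    stop("fragment_length must be 'auto' or a positive number")
  if (!cfg$shift_test %in% c("welch", "student"))
    stop("shift_test must be 'welch' or 'student'")
  cfg
}

#' @rdname pipelineConfig
#' @param cfg a PipelineConfig.
#' @param path file path (flat YAML key-value).
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, x[[k]]))
  invisible(x)
}
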