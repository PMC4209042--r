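# Run configuration: defaults matching the reference analysis settings
# (40-penalty grid, 100 tuning and 100 validation bootstraps, 10
# imputations, 3% tolerance), JSON/YAML loading, and flag overrides.

#' Default run configuration
#'
#' @return named list of all tunable settings with their defaults.
#' @export
default_config <- function() {
  list(
    n_lambda = 40L,           # penalty-grid length
    tolerance_fraction = 0.03,
    n_boot_tune = 100L,       # tuning bootstraps per penalty grid
    n_boot_validate = 100L,   # optimism bootstraps
    m = 10L,                  # imputations
    cycles = 5L,              # chained-equations cycles
    donors = 5L,              # PMM donor-pool size
    seed = NULL,
    verbose = FALSE
  )
}

#' Load a run configuration from file and/or overrides
#'
#' Values resolve as: defaults, overwritten by the file (JSON or YAML),
#' overwritten by `overrides` (e.g. parsed command-line flags). Unknown keys
#' are an error.
#'
#' @param path optional path to a JSON (`.json`) or YAML (`.yml`/`.yaml`)
#'   configuration file.
#' @param overrides named list of final overrides.
#' @return An object of class `run_config` (a validated named list).
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    from_file <- if (grepl("\\.ya?ml$", path)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  for (layer in list(from_file, overrides)) {
    unknown <- setdiff(names(layer), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(layer)] <- layer
  }
  counts <- c("n_lambda", "n_boot_tune", "n_boot_validate", "m", "cycles",
              "donors")
  for (k in counts) {
    cfg[[k]] <- as.integer(cfg[[k]])
    if (cfg[[k]] < 1L) stop(k, " must be >= 1")
  }
  if (cfg$tolerance_fraction < 0) stop("tolerance_fraction must be >= 0")
  structure(cfg, class = "run_config")
}

#' Save a run configuration as JSON
#'
#' @param config a `run_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
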