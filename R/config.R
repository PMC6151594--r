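# Run configuration: one JSON-serializable object describing the batch
# design, effect structure and statistical settings.

#' Default run configuration
#'
#' Assembles the complete configuration of a simulated profiling campaign:
#' channel registry with internal-standard assignment, batch design (wines,
#' methods, replicates, calibration levels, QC cadence, blank counts and
#' runs), gravimetric masses, preparation-effect and instrument parameters,
#' spike certificate values, truth ranges, and statistical settings.
#'
#' @param seed integer seed; mandatory for the simulation commands and kept
#'   `NULL` here so forgetting it is an explicit error rather than a silent
#'   default.
#' @return a named list (class `vinelements_config`).
#' @export
default_config <- function(seed = NULL) {
  cfg <- list(
    seed = seed,
    wines = c("C", "PN", "S", "T"),
    methods = prep_methods(),
    replicates = 3,
    cal_levels = c(0, 1, 10, 50, 100, 500),
    qc_every = 15,
    qc_nominal = 10,
    n_ccb = list(direct = 6, MW = 8),
    n_runs = list(direct = 2, MW = 1),
    mass_sample = 10,
    spike_mass = 0.1,
    alpha = 0.05,
    lod_conf = 0.99,
    channels = assign_internal_standard(),
    truth_ranges = default_truth_ranges(),
    effects = default_method_effects(),
    instrument = default_instrument_params(),
    spikes = default_spike_params()
  )
  class(cfg) <- c("vinelements_config", "list")
  cfg
}

#' Validate a run configuration
#'
#' @param config configuration list.
#' @param require_seed whether a seed must be present (simulation commands).
#' @return the validated configuration, invisibly.
#' @export
validate_config <- function(config, require_seed = FALSE) {
  if (require_seed && (is.null(config$seed) || !is.finite(config$seed))) {
    stop("configuration must carry an integer seed for simulation")
  }
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (is.null(config$channels) || nrow(config$channels) == 0) {
    stop("empty channel registry")
  }
  for (m in config$methods) {
    eff <- config$effects[[m]]
    if (is.null(eff)) stop("no effect parameters for method ", m)
    for (tab_name in c("contamination", "retention")) {
      tab <- eff[[tab_name]]
      if (is.data.frame(tab) && nrow(tab) > 0) {
        known <- paste(config$channels$element, config$channels$mass)
        bad <- setdiff(paste(tab$element, tab$mass), known)
        if (length(bad) > 0) {
          stop(tab_name, " for method ", m,
               " references unknown channels: ", paste(bad, collapse = ", "))
        }
      }
    }
  }
  invisible(config)
}

#' Write a configuration to JSON
#'
#' @param config configuration list.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  # named atomic vectors lose their names as JSON arrays; store the spike
  # abundance vectors as objects instead
  config$spikes <- lapply(config$spikes, function(s) {
    s$abundance <- as.list(s$abundance)
    s
  })
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

.as_df <- function(x, template) {
  if (is.data.frame(x) && nrow(x) > 0) return(x)
  template
}

#' Read a configuration from JSON
#'
#' Restores the native types (named abundance vectors, empty effect tables)
#' that a JSON round trip flattens.
#'
#' @param path JSON file written by [write_config()].
#' @return configuration list (class `vinelements_config`).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  empty_c <- data.frame(element = character(), mass = integer(),
                        mean = numeric(), stringsAsFactors = FALSE)
  empty_r <- data.frame(element = character(), mass = integer(),
                        retention = numeric(), stringsAsFactors = FALSE)
  cfg$effects <- lapply(cfg$effects, function(e) {
    e$contamination <- .as_df(e$contamination, empty_c)
    e$retention <- .as_df(e$retention, empty_r)
    e
  })
  cfg$spikes <- lapply(cfg$spikes, function(s) {
    s$abundance <- unlist(s$abundance)
    s
  })
  cfg$instrument$drift_range <- as.numeric(cfg$instrument$drift_range)
  class(cfg) <- c("vinelements_config", "list")
  cfg
}

#' Hash of a configuration
#'
#' MD5 of the canonical JSON serialization; stamped into every output
#' manifest so a result file can be traced to the exact configuration.
#'
#' @param config configuration list.
#' @return character MD5 digest.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
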