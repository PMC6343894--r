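#' Pipeline configuration
#'
#' `default_config()` returns the full configuration of the analysis
#' pipeline as a nested list: experiment design, flow event, measurement
#' grid, synthetic-trace parameters, asymmetry mode, permutation count and
#' reporting precision. `read_config()` reads a YAML file with the same
#' structure and merges it over the defaults, so a config file needs to
#' state only what it overrides. A template YAML mirroring the defaults
#' ships in `inst/extdata/default_config.yaml`.
#'
#' @param path Path to a YAML configuration file.
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    design = list(
      treatments = c("R0HP", "R1HP", "R1BF", "R2HP", "R2BF"),
      replicates = 5L,
      school_size = 5L,
      event_duration = 2400,
      acclimation = 1800
    ),
    flow = list(
      peak_discharge = 60,
      base_discharge = 7,
      up_ramp_duration = 28.12,
      depth_increase = 15.7
    ),
    grid = list(
      n_rows = 15L,
      n_cols = 3L,
      flume_width = 0.7,
      reach_length = 6.5,
      wake_length = 3L
    ),
    trace = list(
      base_velocity = 0.1,
      base_depth = 0.1,
      sampling_rate = 200,
      duration = 60,
      turbulence_floor = 1,
      turbulence_coef = 0.12,
      wake_velocity_factor = 0.3,
      side_velocity_factor = 1.3,
      background_vortex = 1,
      wake_vortex_base = 8,
      wake_vortex_coef = 0.05,
      vortex_scale = c(R1 = 1, R2 = 1.6),
      strouhal = 0.2
    ),
    asymmetry_mode = "pairmean",
    n_permutations = 999L,
    rounding = list(stats = 3L, pressure = 2L)
  )
}

#' @rdname default_config
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  if (!is.list(override)) return(override)
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]]))
      merge_lists(base[[nm]], override[[nm]])
    else override[[nm]]
  }
  base
}
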