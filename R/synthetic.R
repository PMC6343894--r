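#' Scenario for a synthetic LLP pressure trace
#'
#' Describes the flow conditions a synthetic lateral-line-probe recording
#' should encode: the front-pair mean follows the dynamic pressure
#' \eqn{q = \frac{1}{2}\rho v^2}, Gaussian fluctuation amplitude encodes
#' turbulence, and an antiphase sinusoid on each lateral pair encodes vortex
#' shedding at a fixed frequency. The absolute channel carries the
#' hydrostatic head \eqn{\rho g h}.
#'
#' @param mean_velocity Mean flow velocity in m/s (>= 0).
#' @param turbulence_sd Standard deviation of the Gaussian pressure noise, Pa.
#' @param vortex_amplitude Amplitude of the shed-vortex pressure signal, Pa.
#' @param shedding_frequency Vortex shedding frequency, Hz; must be below
#'   half the sampling rate so the oscillation is resolvable.
#' @param sampling_rate Sampling rate in Hz (default 200, the probe's rate).
#' @param duration Recording length in seconds (default 60 s per grid cell).
#' @param depth Water depth in m (for the absolute channel).
#' @param water_density Water density in kg/m^3 (default 1000).
#' @param gravity Gravitational acceleration in m/s^2 (default 9.81).
#' @param seed Integer seed making the generated trace reproducible.
#' @return An object of class `trace_scenario`.
#' @examples
#' sc <- trace_scenario(mean_velocity = 0.5, turbulence_sd = 0, seed = 1)
#' tr <- generate_llp_trace(sc)
#' mean_front_pressure(tr) # 125 Pa = 0.5 * 1000 * 0.5^2
#' @export
trace_scenario <- function(mean_velocity,
                           turbulence_sd = 5,
                           vortex_amplitude = 0,
                           shedding_frequency = 10,
                           sampling_rate = 200,
                           duration = 60,
                           depth = 0.1,
                           water_density = 1000,
                           gravity = 9.81,
                           seed = NULL) {
  num1 <- function(x, nm, min = 0, strict = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (strict && x <= min) || (!strict && x < min))
      stop_invalid("'", nm, "' must be a finite scalar ",
                   if (strict) "> " else ">= ", min)
    x
  }
  num1(mean_velocity, "mean_velocity")
  num1(turbulence_sd, "turbulence_sd")
  num1(vortex_amplitude, "vortex_amplitude")
  num1(shedding_frequency, "shedding_frequency")
  num1(sampling_rate, "sampling_rate", strict = TRUE)
  num1(duration, "duration", strict = TRUE)
  num1(depth, "depth")
  num1(water_density, "water_density", strict = TRUE)
  num1(gravity, "gravity")
  if (sampling_rate <= 2 * shedding_frequency)
    stop_invalid("sampling_rate must exceed twice the shedding frequency ",
                 "(otherwise the oscillation is not resolvable)")
  structure(
    list(mean_velocity = mean_velocity,
         turbulence_sd = turbulence_sd,
         vortex_amplitude = vortex_amplitude,
         shedding_frequency = shedding_frequency,
         sampling_rate = sampling_rate,
         duration = duration,
         depth = depth,
         water_density = water_density,
         gravity = gravity,
         seed = seed),
    class = "trace_scenario"
  )
}

#' Generate a synthetic LLP pressure trace
#'
#' Builds a six-channel differential pressure recording (plus absolute
#' channel) realising a [trace_scenario()]:
#' \itemize{
#'   \item front pair (sensors 1, 2): dynamic-pressure baseline
#'     \eqn{\frac{1}{2}\rho v^2}, Gaussian noise, and an *in-phase*
#'     oscillation at the shedding frequency (both nose sensors see the
#'     passing structure identically, so the front pair contributes no
#'     asymmetry);
#'   \item lateral pairs (3,4) and (5,6): zero-mean Gaussian noise plus an
#'     *antiphase* sinusoid of amplitude `vortex_amplitude` — the odd sensor
#'     of each pair gets `+`, the even sensor `-` — mimicking vortices shed
#'     alternately down the two flanks;
#'   \item absolute channel: hydrostatic constant \eqn{\rho g h} plus noise.
#' }
#' The same scenario and seed always produce a bit-identical trace.
#'
#' @param scenario A [trace_scenario()].
#' @param treatment,grid_row,grid_col Optional metadata copied to the trace.
#' @return A [sensor_trace()].
#' @export
generate_llp_trace <- function(scenario,
                               treatment = NA_character_,
                               grid_row = NA_integer_,
                               grid_col = NA_integer_) {
  if (!inherits(scenario, "trace_scenario"))
    stop_invalid("'scenario' must be a trace_scenario object")
  n <- max(1L, round(scenario$sampling_rate * scenario$duration))
  t <- (seq_len(n) - 1L) / scenario$sampling_rate
  q <- 0.5 * scenario$water_density * scenario$mean_velocity^2
  osc <- scenario$vortex_amplitude * sin(2 * pi * scenario$shedding_frequency * t)
  sd <- scenario$turbulence_sd
  with_seed(scenario$seed, {
    noise <- function() if (sd > 0) stats::rnorm(n, 0, sd) else numeric(n)
    p <- cbind(q + osc + noise(),  # sensor 1 (front)
               q + osc + noise(),  # sensor 2 (front, in phase)
               +osc + noise(),     # sensor 3
               -osc + noise(),     # sensor 4 (antiphase partner)
               +osc + noise(),     # sensor 5
               -osc + noise())     # sensor 6
    p_abs <- scenario$water_density * scenario$gravity * scenario$depth + noise()
    sensor_trace(p, sampling_rate = scenario$sampling_rate, p_abs = p_abs,
                 treatment = treatment, grid_row = grid_row, grid_col = grid_col)
  })
}

#' Generate a full measurement-grid pressure field for one treatment
#'
#' Produces one synthetic [sensor_trace()] per grid cell, with the spatial
#' structure the experiment creates: cells in the wake of an instream
#' structure get reduced velocity (refuge effect) and elevated vortex
#' amplitude (shed vortices); cells beside a structure get locally
#' accelerated flow; hydropeaking scales all cell velocities by the flow
#' ratio relative to base flow and raises the water depth. Without
#' structures (`R0`) the field is homogeneous. V-shaped structures (`R2`)
#' shed larger vortices than solid pyramids (`R1`).
#'
#' @param layout A [build_grid()] layout (its `configuration` attribute
#'   must match the treatment's configuration).
#' @param treatment Treatment label, e.g. `"R1BF"`.
#' @param seed Integer seed; each cell derives its own sub-seed, so the
#'   whole field is reproducible.
#' @param flow A [flow_event()] giving discharges and the depth increase.
#' @param base_velocity Mean velocity (m/s) of the unobstructed field under
#'   base flow.
#' @param base_depth Water depth (m) under base flow.
#' @param duration,sampling_rate Per-cell recording length (s) and rate (Hz).
#' @param turbulence_floor,turbulence_coef Turbulence noise sd is
#'   `floor + coef * q` with `q` the local dynamic pressure (Pa).
#' @param wake_velocity_factor,side_velocity_factor Velocity multipliers for
#'   wake and structure-adjacent cells.
#' @param background_vortex Vortex amplitude (Pa) away from structures.
#' @param wake_vortex_base,wake_vortex_coef Wake vortex amplitude is
#'   `scale * (base + coef * q)`.
#' @param vortex_scale Named multipliers per configuration (`R1`, `R2`).
#' @param strouhal Strouhal number setting the shedding frequency
#'   `St * v / L` for body length `L` = 0.22 m (clamped to 0.5-20 Hz).
#' @return Named list of [sensor_trace()] objects (`"r<row>c<col>"`), one
#'   per grid cell.
#' @export
generate_field_scenario <- function(layout, treatment, seed,
                                    flow = flow_event(),
                                    base_velocity = 0.1,
                                    base_depth = 0.1,
                                    duration = 60,
                                    sampling_rate = 200,
                                    turbulence_floor = 1,
                                    turbulence_coef = 0.12,
                                    wake_velocity_factor = 0.3,
                                    side_velocity_factor = 1.3,
                                    background_vortex = 1,
                                    wake_vortex_base = 8,
                                    wake_vortex_coef = 0.05,
                                    vortex_scale = c(R1 = 1, R2 = 1.6),
                                    strouhal = 0.2) {
  if (!inherits(layout, "grid_layout"))
    stop_invalid("'layout' must be a grid_layout object")
  if (!is.character(treatment) || length(treatment) != 1L ||
      !grepl("^R[0-2](HP|BF)$", treatment))
    stop_invalid("unknown treatment label: ", treatment)
  config <- treatment_configuration(treatment)
  event <- treatment_event(treatment)
  if (!identical(attr(layout, "configuration"), config))
    stop_invalid("layout configuration (", attr(layout, "configuration"),
                 ") does not match treatment ", treatment)

  mult <- if (event == "HP") flow_ratio(flow$peak_discharge, flow$base_discharge) else 1
  depth <- base_depth + if (event == "HP") flow$depth_increase / 100 else 0
  vscale <- if (config == "R0") 1 else unname(vortex_scale[config])
  structures <- attr(layout, "structures")
  side <- side_cells(layout)

  traces <- vector("list", nrow(layout))
  names(traces) <- sprintf("r%dc%d", layout$grid_row, layout$grid_col)
  for (i in seq_len(nrow(layout))) {
    row <- layout$grid_row[i]; col <- layout$grid_col[i]
    in_wake <- layout$area_class[i] == "structure_wake"
    in_side <- any(side$grid_row == row & side$grid_col == col)
    vf <- if (in_wake) wake_velocity_factor else if (in_side) side_velocity_factor else 1
    v <- base_velocity * mult * vf
    q <- 0.5 * 1000 * v^2
    amp <- if (in_wake) vscale * (wake_vortex_base + wake_vortex_coef * q)
           else background_vortex
    freq <- min(20, max(0.5, strouhal * v / 0.22))
    sc <- trace_scenario(mean_velocity = v,
                         turbulence_sd = turbulence_floor + turbulence_coef * q,
                         vortex_amplitude = amp,
                         shedding_frequency = freq,
                         sampling_rate = sampling_rate,
                         duration = duration,
                         depth = depth,
                         seed = (seed + 1009L * row + col) %% .Machine$integer.max)
    traces[[i]] <- generate_llp_trace(sc, treatment = treatment,
                                      grid_row = row, grid_col = col)
  }
  traces
}

#' Treatment effect specification for synthetic observations
#'
#' Holds the expected behaviour-metric counts per 40-minute event and the
#' physiology means/SDs per treatment used by the synthetic observation
#' generators. Structure-use metrics are undefined (`NA`, "absent") for the
#' `R0` configuration, which has no structures to use. Defaults encode the
#' qualitative pattern of the study: individual structure use highest under
#' hydropeaking with structures, group structure use favoured by solid
#' pyramids, sprints and drifts stimulated by hydropeaking, and a lactate
#' elevation specific to `R2HP` (mean 5.06 mM, SD 0.49 mM).
#'
#' @param behaviour_means Numeric matrix, 10 behaviour metrics x treatments,
#'   of expected counts per event; `NA` marks metric/treatment combinations
#'   that are absent by design.
#' @param dispersion Negative-binomial size parameter shared by all counts
#'   (larger = closer to Poisson; `Inf` gives exactly Poisson). Default 5.
#' @param physiology Data frame with columns `treatment`, `glucose_mean`,
#'   `glucose_sd` (mg/dl), `lactate_mean`, `lactate_sd` (mM).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(behaviour_means = default_behaviour_means(),
                        dispersion = 5,
                        physiology = default_physiology_effects()) {
  if (!is.matrix(behaviour_means) || is.null(rownames(behaviour_means)) ||
      is.null(colnames(behaviour_means)))
    stop_invalid("'behaviour_means' must be a metric x treatment matrix with dimnames")
  if (!all(rownames(behaviour_means) %in% behaviour_metric_sets()$all))
    stop_invalid("unknown behaviour metric in 'behaviour_means'")
  if (any(behaviour_means < 0, na.rm = TRUE))
    stop_invalid("behaviour means must be >= 0")
  if (!is.numeric(dispersion) || length(dispersion) != 1L || dispersion <= 0)
    stop_invalid("'dispersion' must be a positive scalar")
  req <- c("treatment", "glucose_mean", "glucose_sd", "lactate_mean", "lactate_sd")
  if (!is.data.frame(physiology) || !all(req %in% names(physiology)))
    stop_invalid("'physiology' must have columns ", paste(req, collapse = ", "))
  if (any(physiology$glucose_sd <= 0) || any(physiology$lactate_sd <= 0))
    stop_invalid("physiology SDs must be > 0")
  if (any(physiology$glucose_mean < 0) || any(physiology$lactate_mean < 0))
    stop_invalid("physiology means must be >= 0")
  structure(list(behaviour_means = behaviour_means,
                 dispersion = dispersion,
                 physiology = physiology),
            class = "effect_spec")
}

#' @rdname effect_spec
#' @export
default_behaviour_means <- function() {
  metrics <- behaviour_metric_sets()
  treatments <- c("R0HP", "R1HP", "R1BF", "R2HP", "R2BF")
  m <- matrix(NA_real_, length(metrics$all), length(treatments),
              dimnames = list(metrics$all, treatments))
  #                 R0HP R1HP R1BF R2HP R2BF
  m["Iref", ]    <- c(NA,  30,  12,  25,   8)
  m["Gref", ]    <- c(NA,  18,  20,   8,   6)
  m["Imiddle", ] <- c(NA,  12,   8,  20,   6)
  m["Gmiddle", ] <- c(NA,   6,   5,   6,   4)
  m["Iwall", ]   <- c(NA,   8,   6,  14,   5)
  m["Gwall", ]   <- c(NA,   4,   3,   6,   3)
  m["Isprint", ] <- c(25,  22,  10,  18,   6)
  m["Gsprint", ] <- c(12,  10,  14,   8,   5)
  m["Idrift", ]  <- c(22,  20,   8,  10,   6)
  m["Gdrift", ]  <- c(15,  14,   6,   7,   4)
  m
}

#' @rdname effect_spec
#' @export
default_physiology_effects <- function() {
  data.frame(
    treatment = c("R0HP", "R1HP", "R1BF", "R2HP", "R2BF"),
    glucose_mean = c(51, 49, 45, 49, 47),
    glucose_sd = c(8, 8, 8, 8, 8),
    lactate_mean = c(3.9, 4.0, 3.8, 5.06, 3.9),
    lactate_sd = c(0.9, 0.9, 0.9, 0.49, 0.9),
    stringsAsFactors = FALSE
  )
}

#' Generate synthetic behaviour-metric counts
#'
#' Draws absolute frequencies of the ten behaviour metrics for every
#' replicate school of every treatment from a negative-binomial law with
#' the per-metric, per-treatment means of an [effect_spec()] (shared
#' dispersion). Metric/treatment combinations that the spec marks absent
#' (structure-use metrics under `R0`) yield `NA` counts, not zeros.
#'
#' @param design An [experiment_design()].
#' @param effects An [effect_spec()]; must define every design treatment.
#' @param seed Integer seed.
#' @return A `frequency_table` data frame with columns `treatment`,
#'   `replicate`, `metric`, `count`.
#' @export
generate_behaviour_counts <- function(design, effects, seed) {
  stopifnot(inherits(design, "experiment_design"), inherits(effects, "effect_spec"))
  missing_tr <- setdiff(design$treatments, colnames(effects$behaviour_means))
  if (length(missing_tr))
    stop_invalid("effect spec lacks treatments: ", paste(missing_tr, collapse = ", "))
  metrics <- rownames(effects$behaviour_means)
  structure_set <- behaviour_metric_sets()$structure
  grid <- expand.grid(metric = metrics,
                      replicate = seq_len(design$replicates),
                      treatment = design$treatments,
                      stringsAsFactors = FALSE)
  mu <- effects$behaviour_means[cbind(grid$metric, grid$treatment)]
  absent <- treatment_configuration(grid$treatment) == "R0" &
    grid$metric %in% structure_set
  if (any(!absent & is.na(mu)))
    stop_invalid("effect mean undefined for a non-absent metric/treatment combination")
  size <- effects$dispersion
  counts <- rep(NA_real_, nrow(grid))
  with_seed(seed, {
    idx <- which(!absent)
    counts[idx] <- if (is.infinite(size)) stats::rpois(length(idx), mu[idx])
                   else stats::rnbinom(length(idx), size = size, mu = mu[idx])
  })
  out <- data.frame(treatment = grid$treatment,
                    replicate = grid$replicate,
                    metric = grid$metric,
                    count = as.integer(counts),
                    stringsAsFactors = FALSE)
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Generate synthetic physiology samples
#'
#' One record per fish (`replicates x school_size` per treatment), with
#' blood glucose (mg/dl) and lactate (mM) drawn from per-treatment Gaussian
#' laws truncated at zero (negative draws are resampled; physiological
#' concentrations cannot be negative).
#'
#' @inheritParams generate_behaviour_counts
#' @return Data frame with columns `fish_id`, `treatment`, `replicate`,
#'   `glucose`, `lactate`.
#' @export
generate_physiology <- function(design, effects, seed) {
  stopifnot(inherits(design, "experiment_design"), inherits(effects, "effect_spec"))
  phys <- effects$physiology
  missing_tr <- setdiff(design$treatments, phys$treatment)
  if (length(missing_tr))
    stop_invalid("effect spec lacks physiology for: ", paste(missing_tr, collapse = ", "))
  rows <- expand.grid(fish = seq_len(design$school_size),
                      replicate = seq_len(design$replicates),
                      treatment = design$treatments,
                      stringsAsFactors = FALSE)
  i <- match(rows$treatment, phys$treatment)
  rtruncnorm <- function(n, mean, sd) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < 0)) x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
    x
  }
  with_seed(seed, {
    glucose <- rtruncnorm(nrow(rows), phys$glucose_mean[i], phys$glucose_sd[i])
    lactate <- rtruncnorm(nrow(rows), phys$lactate_mean[i], phys$lactate_sd[i])
  })
  data.frame(
    fish_id = sprintf("%s_r%d_f%d", rows$treatment, rows$replicate, rows$fish),
    treatment = rows$treatment,
    replicate = rows$replicate,
    glucose = glucose,
    lactate = lactate,
    stringsAsFactors = FALSE
  )
}
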