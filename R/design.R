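#' Experimental design of a hydropeaking flume study
#'
#' Describes the treatment structure of a flume experiment in which schools of
#' fish are exposed to a flow event (hydropeaking `HP` or base flow `BF`)
#' crossed with an instream-structure configuration (`R0` none, `R1` solid
#' triangular pyramids, `R2` v-shaped structures). The untested combination
#' `R0BF` is rejected: without structures, base flow offers no contrast of
#' interest and the study design never includes it.
#'
#' @param treatments Character vector of treatment labels, each of the form
#'   `"<configuration><event>"`, e.g. `"R1HP"`. Defaults to the five
#'   treatments of the study design.
#' @param replicates Number of replicate schools per treatment (default 5).
#' @param school_size Number of fish per school (default 5).
#' @param event_duration Flow-event duration in seconds (default 2400 s,
#'   i.e. 40 minutes).
#' @param acclimation Acclimation period before the event in seconds
#'   (default 1800 s, i.e. 30 minutes).
#' @return An object of class `experiment_design`.
#' @examples
#' d <- experiment_design()
#' treatment_configuration(d$treatments)
#' @export
experiment_design <- function(treatments = c("R0HP", "R1HP", "R1BF", "R2HP", "R2BF"),
                              replicates = 5L,
                              school_size = 5L,
                              event_duration = 2400,
                              acclimation = 1800) {
  if (!is.character(treatments) || length(treatments) < 1L)
    stop_invalid("'treatments' must be a non-empty character vector")
  if (anyDuplicated(treatments))
    stop_invalid("treatment labels must be unique")
  bad <- treatments[!grepl("^R[0-2](HP|BF)$", treatments)]
  if (length(bad))
    stop_invalid("invalid treatment label(s): ", paste(bad, collapse = ", "),
                 " (expected R{0,1,2} followed by HP or BF)")
  if ("R0BF" %in% treatments)
    stop_invalid("treatment R0BF is not part of the design (never tested)")
  if (!is_count(replicates) || replicates < 1)
    stop_invalid("'replicates' must be a positive integer")
  if (!is_count(school_size) || school_size < 1)
    stop_invalid("'school_size' must be a positive integer")
  for (nm in c("event_duration", "acclimation")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_invalid("'", nm, "' must be a positive duration in seconds")
  }
  structure(
    list(treatments = treatments,
         replicates = as.integer(replicates),
         school_size = as.integer(school_size),
         event_duration = event_duration,
         acclimation = acclimation),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("Hydropeaking flume experiment design\n")
  cat("  treatments:    ", paste(x$treatments, collapse = ", "), "\n")
  cat("  replicates:    ", x$replicates, "schools per treatment\n")
  cat("  school size:   ", x$school_size, "fish\n")
  cat("  event duration:", x$event_duration, "s; acclimation:", x$acclimation, "s\n")
  invisible(x)
}

#' Decompose treatment labels
#'
#' @param treatments Character vector of treatment labels such as `"R1HP"`.
#' @return `treatment_configuration()` returns the structure configuration
#'   (`"R0"`, `"R1"`, `"R2"`); `treatment_event()` the flow event
#'   (`"HP"` or `"BF"`).
#' @export
treatment_configuration <- function(treatments) substr(treatments, 1L, 2L)

#' @rdname treatment_configuration
#' @export
treatment_event <- function(treatments) substr(treatments, 3L, 4L)

#' Flow-event description
#'
#' Holds the discharge and ramping characteristics of a simulated
#' hydropeaking event. Defaults are the study conditions: a single up-ramp
#' from a 7 l/s base flow to a sustained 60 l/s peak over 28.12 s, raising
#' the water depth by 15.7 cm.
#'
#' @param peak_discharge Peak discharge in l/s.
#' @param base_discharge Base-flow discharge in l/s.
#' @param up_ramp_duration Duration of the up-ramping stage in seconds.
#' @param depth_increase Total water-depth increase during up-ramping in cm.
#' @return An object of class `flow_event`.
#' @examples
#' fe <- flow_event()
#' flow_ratio(fe$peak_discharge, fe$base_discharge)
#' @export
flow_event <- function(peak_discharge = 60,
                       base_discharge = 7,
                       up_ramp_duration = 28.12,
                       depth_increase = 15.7) {
  if (!is.numeric(base_discharge) || base_discharge <= 0)
    stop_invalid("'base_discharge' must be > 0")
  if (!is.numeric(peak_discharge) || peak_discharge < base_discharge)
    stop_invalid("'peak_discharge' must be >= base_discharge")
  if (!is.numeric(up_ramp_duration) || up_ramp_duration <= 0)
    stop_invalid("'up_ramp_duration' must be > 0")
  if (!is.numeric(depth_increase) || depth_increase < 0)
    stop_invalid("'depth_increase' must be >= 0")
  structure(
    list(peak_discharge = peak_discharge,
         base_discharge = base_discharge,
         up_ramp_duration = up_ramp_duration,
         depth_increase = depth_increase),
    class = "flow_event"
  )
}

#' @export
print.flow_event <- function(x, ...) {
  cat("Flow event:", x$base_discharge, "->", x$peak_discharge, "l/s\n")
  cat("  flow ratio:     ",
      report_round(flow_ratio(x$peak_discharge, x$base_discharge), 1), "\n")
  cat("  up-ramping rate:",
      report_round(up_ramping_rate(x$depth_increase, x$up_ramp_duration), 2),
      "cm/s over", x$up_ramp_duration, "s\n")
  invisible(x)
}

#' Flow ratio of a hydropeaking event
#'
#' The flow ratio is the peak discharge divided by the base-flow discharge,
#' a standard severity measure for hydropeaking. For the study conditions
#' (60 and 7 l/s) the ratio is 60/7 = 8.57, reported as 8.6 at one decimal.
#'
#' @param peak_discharge Peak discharge (l/s), > 0.
#' @param base_discharge Base-flow discharge (l/s), > 0.
#' @return Dimensionless ratio (unrounded).
#' @export
flow_ratio <- function(peak_discharge, base_discharge) {
  if (!is.numeric(peak_discharge) || !is.numeric(base_discharge) ||
      any(peak_discharge <= 0) || any(base_discharge <= 0))
    stop_invalid("discharges must be positive")
  peak_discharge / base_discharge
}

#' Up-ramping rate
#'
#' Rate of water-depth rise during the discharge increase, in cm/s. For the
#' study conditions (15.7 cm over 28.12 s) this is 0.558 cm/s.
#'
#' @param depth_increase Water-depth increase (cm), >= 0.
#' @param duration Up-ramping duration (s), > 0.
#' @return Rate in cm/s (unrounded).
#' @export
up_ramping_rate <- function(depth_increase, duration) {
  if (!is.numeric(duration) || any(duration <= 0))
    stop_invalid("'duration' must be positive")
  if (!is.numeric(depth_increase) || any(depth_increase < 0))
    stop_invalid("'depth_increase' must be >= 0")
  depth_increase / duration
}
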