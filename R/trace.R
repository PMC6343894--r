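#' Six-channel lateral line probe recording
#'
#' Container for one grid-cell recording from the artificial lateral line
#' probe (LLP): six differential pressure channels sampled simultaneously,
#' plus an optional absolute-pressure channel used for water depth. Sensors
#' are 1-indexed following the probe layout; the fixed pairing is (1,2) on
#' the nose (front pair) and (3,4), (5,6) along the left/right flanks.
#'
#' @param pressure Numeric matrix, `n` samples x 6 sensors, in Pa.
#' @param sampling_rate Sampling rate in Hz (> 0; the probe records at 200 Hz).
#' @param p_abs Optional numeric vector of length `n`, absolute pressure in Pa.
#' @param treatment,grid_row,grid_col Optional metadata identifying the
#'   treatment and the measurement-grid cell the trace belongs to.
#' @return An object of class `sensor_trace`.
#' @examples
#' tr <- sensor_trace(matrix(rnorm(60), 10, 6), sampling_rate = 200)
#' mean_front_pressure(tr)
#' @export
sensor_trace <- function(pressure, sampling_rate,
                         p_abs = NULL,
                         treatment = NA_character_,
                         grid_row = NA_integer_,
                         grid_col = NA_integer_) {
  pressure <- as.matrix(pressure)
  if (!is.numeric(pressure) || ncol(pressure) != 6L)
    stop_invalid("'pressure' must be a numeric n x 6 matrix (one column per sensor)")
  if (nrow(pressure) < 1L)
    stop_invalid("a sensor trace needs at least one sample")
  if (anyNA(pressure) || any(!is.finite(pressure)))
    stop_invalid("pressure samples must all be finite")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop_invalid("'sampling_rate' must be a positive scalar (Hz)")
  if (!is.null(p_abs)) {
    if (!is.numeric(p_abs) || length(p_abs) != nrow(pressure))
      stop_invalid("'p_abs' must be numeric with one value per sample")
  }
  structure(
    list(pressure = unname(pressure),
         p_abs = p_abs,
         sampling_rate = sampling_rate,
         treatment = treatment,
         grid_row = as.integer(grid_row),
         grid_col = as.integer(grid_col)),
    class = "sensor_trace"
  )
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat("LLP sensor trace:", nrow(x$pressure), "samples x 6 channels @",
      x$sampling_rate, "Hz\n")
  if (!is.na(x$treatment))
    cat("  treatment", x$treatment, "cell (", x$grid_row, ",", x$grid_col, ")\n")
  cat("  channel means (Pa):",
      paste(sprintf("%.2f", colMeans(x$pressure)), collapse = " "), "\n")
  invisible(x)
}

n_samples <- function(trace) nrow(trace$pressure)

check_trace <- function(trace) {
  if (!inherits(trace, "sensor_trace"))
    stop_invalid("expected a 'sensor_trace' object")
  if (n_samples(trace) < 1L) stop_invalid("empty trace")
  invisible(trace)
}
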