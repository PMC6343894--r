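#' Measurement-grid layout of the flume
#'
#' Builds the grid of LLP measurement cells covering the usable flume reach.
#' The default is 15 streamwise rows x 3 lateral columns = 45 cells, cell
#' dimensions close to the probe body length (0.7 m width / 3 = 0.233 m
#' lateral). Observation zones `C1`..`C5` are streamwise bands, `C1` most
#' upstream. For configurations with instream structures (`R1`, `R2`), three
#' structures are placed in an alternating pattern and the three cells
#' immediately downstream of each are designated its wake ("structure
#' area", 9 cells); all remaining cells are the "flume area" (36 cells by
#' default). The two areas partition the grid.
#'
#' Coordinates: row 1 is most upstream; column 1 is the left wall looking
#' downstream.
#'
#' @param configuration `"R0"` (no structures), `"R1"` or `"R2"`.
#' @param n_rows,n_cols Grid dimensions (defaults 15 x 3).
#' @param flume_width,reach_length Flume dimensions in m (0.7 and 6.5).
#' @param structures Data frame with columns `row`, `col` giving structure
#'   cell positions, or `NULL` to use the default alternating placement
#'   (none for `R0`).
#' @param wake_length Number of straight-downstream cells per structure
#'   counted as its wake (default 3).
#' @return A `grid_layout`: a data frame with one row per cell (`grid_row`,
#'   `grid_col`, `zone`, `area_class`), carrying the configuration,
#'   structure positions and cell dimensions as attributes.
#' @examples
#' g <- build_grid("R1")
#' table(g$area_class) # 9 wake cells, 36 flume cells
#' @export
build_grid <- function(configuration = c("R1", "R2", "R0"),
                       n_rows = 15L, n_cols = 3L,
                       flume_width = 0.7, reach_length = 6.5,
                       structures = NULL,
                       wake_length = 3L) {
  configuration <- match.arg(configuration)
  if (!is_count(n_rows) || n_rows < 1 || !is_count(n_cols) || n_cols < 1)
    stop_invalid("grid dimensions must be positive integers")
  if (flume_width <= 0 || reach_length <= 0)
    stop_invalid("flume dimensions must be positive")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)

  if (is.null(structures)) {
    structures <- if (configuration == "R0") {
      data.frame(row = integer(0), col = integer(0))
    } else {
      default_structures(n_rows, n_cols)
    }
  }
  if (configuration == "R0" && nrow(structures) > 0)
    stop_invalid("configuration R0 has no instream structures")
  if (nrow(structures) > 0 &&
      (any(structures$row < 1 | structures$row > n_rows) ||
       any(structures$col < 1 | structures$col > n_cols)))
    stop_invalid("structure positions outside the grid")

  cells <- expand.grid(grid_col = seq_len(n_cols), grid_row = seq_len(n_rows))
  cells <- cells[, c("grid_row", "grid_col")]
  band <- ceiling(n_rows / 5)
  cells$zone <- paste0("C", pmin(5L, ceiling(cells$grid_row / band)))

  wake <- wake_cells_for(structures, wake_length, n_rows, n_cols)
  key <- paste(cells$grid_row, cells$grid_col)
  cells$area_class <- ifelse(key %in% paste(wake$grid_row, wake$grid_col),
                             "structure_wake", "flume")
  rownames(cells) <- NULL
  structure(cells,
            configuration = configuration,
            structures = structures,
            wake_length = as.integer(wake_length),
            n_rows = n_rows, n_cols = n_cols,
            cell_length = reach_length / n_rows,
            cell_width = flume_width / n_cols,
            class = c("grid_layout", "data.frame"))
}

# Default alternating structure placement: three structures on alternating
# sides of the channel, spaced three rows apart, leaving room for a full
# wake downstream of each.
default_structures <- function(n_rows, n_cols) {
  if (n_rows < 6L || n_cols < 1L)
    return(data.frame(row = integer(0), col = integer(0)))
  rows <- c(3L, 6L, 9L)
  rows <- rows[rows <= n_rows - 3L]
  cols <- rep_len(c(1L, n_cols), length(rows))
  data.frame(row = rows, col = cols)
}

# Cells designated "behind" each structure: the straight-downstream run of
# `wake_length` cells in the structure's own column.
wake_cells_for <- function(structures, wake_length, n_rows, n_cols) {
  if (nrow(structures) == 0)
    return(data.frame(grid_row = integer(0), grid_col = integer(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(structures)), function(i) {
    rows <- structures$row[i] + seq_len(wake_length)
    if (any(rows > n_rows))
      stop_invalid("wake of structure at row ", structures$row[i],
                   " extends beyond the grid")
    data.frame(grid_row = rows, grid_col = structures$col[i])
  }))
  if (anyDuplicated(paste(out$grid_row, out$grid_col)))
    stop_invalid("overlapping structure wakes")
  out
}

# Cells laterally adjacent to a structure (same row, other columns), where
# flow locally accelerates around the obstruction.
side_cells <- function(layout) {
  structures <- attr(layout, "structures")
  if (nrow(structures) == 0)
    return(data.frame(grid_row = integer(0), grid_col = integer(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(structures)), function(i) {
    cols <- setdiff(seq_len(attr(layout, "n_cols")), structures$col[i])
    if (!length(cols)) return(NULL)
    data.frame(grid_row = structures$row[i], grid_col = cols)
  }))
  out %||% data.frame(grid_row = integer(0), grid_col = integer(0))
}

#' Map per-cell summaries onto the measurement grid
#'
#' Joins a set of [summarize_cell()] results (or an equivalent data frame in
#' the canonical summary schema) to a [build_grid()] layout, validating that
#' every grid cell is present exactly once and that all summaries share one
#' treatment and one asymmetry mode.
#'
#' @param summaries A list of `cell_summary` objects, or a data frame with
#'   columns `treatment`, `grid_row`, `grid_col`, `p_front_mean`,
#'   `p_front_fluct`, `p_asym`, `p_asym_log`.
#' @param layout A [build_grid()] layout.
#' @param mode Asymmetry mode tag when `summaries` is a plain data frame
#'   (ignored for `cell_summary` input, which carries its own).
#' @return A `field_map`: data frame with the layout columns plus the four
#'   derived variables; attributes `treatment`, `mode`, `layout`.
#' @export
field_map <- function(summaries, layout, mode = "pairmean") {
  if (!inherits(layout, "grid_layout"))
    stop_invalid("'layout' must be a grid_layout object")
  if (is.list(summaries) && !is.data.frame(summaries) &&
      all(vapply(summaries, inherits, logical(1), "cell_summary"))) {
    modes <- unique(vapply(summaries, `[[`, character(1), "mode"))
    if (length(modes) != 1L)
      stop_invalid("all cell summaries must share one asymmetry mode")
    mode <- modes
    summaries <- do.call(rbind, lapply(summaries, as.data.frame))
  }
  req <- c("treatment", "grid_row", "grid_col",
           "p_front_mean", "p_front_fluct", "p_asym", "p_asym_log")
  miss <- setdiff(req, names(summaries))
  if (length(miss))
    stop_invalid("summary table lacks column(s): ", paste(miss, collapse = ", "))
  if (length(unique(summaries$treatment)) != 1L)
    stop_invalid("a field map holds exactly one treatment")

  key_l <- paste(layout$grid_row, layout$grid_col)
  key_s <- paste(summaries$grid_row, summaries$grid_col)
  if (anyDuplicated(key_s))
    stop_invalid("duplicate cell(s) in summaries: ",
                 paste(unique(key_s[duplicated(key_s)]), collapse = "; "))
  missing_cells <- setdiff(key_l, key_s)
  if (length(missing_cells))
    stop_invalid("incomplete map; missing cell(s) (row col): ",
                 paste(missing_cells, collapse = "; "))
  extra <- setdiff(key_s, key_l)
  if (length(extra))
    stop_invalid("summaries for cells outside the layout: ",
                 paste(extra, collapse = "; "))

  out <- cbind(as.data.frame(layout),
               summaries[match(key_l, key_s),
                         c("p_front_mean", "p_front_fluct", "p_asym", "p_asym_log")])
  rownames(out) <- NULL
  structure(out,
            treatment = summaries$treatment[1],
            mode = mode,
            layout = layout,
            class = c("field_map", "data.frame"))
}

#' Summarise a whole grid of traces into a field map
#'
#' Convenience wrapper: applies [summarize_cell()] to every trace in a
#' collection (e.g. from [generate_field_scenario()]) and assembles the
#' [field_map()].
#'
#' @param traces List of [sensor_trace()] objects with grid metadata.
#' @inheritParams summarize_cell
#' @param layout A [build_grid()] layout.
#' @return A `field_map`.
#' @export
summarize_field <- function(traces, layout, mode = "pairmean") {
  field_map(lapply(traces, summarize_cell, mode = mode), layout)
}

map_variables <- c("p_front_mean", "p_front_fluct", "p_asym_log")

#' Structure-area and flume-area summaries of a field map
#'
#' `summarize_structure_area()` returns, for each pressure variable (front
#' pressure, front fluctuations, log asymmetry), the minimum over the wake
#' cells behind the structures — the most sheltered conditions a refuge
#' offers. `summarize_flume_area()` returns the mean and sample SD (n-1
#' denominator) over all non-wake cells — the ambient conditions in the
#' flume. Together the two summaries use every cell exactly once. For a
#' structure-free (`R0`) layout the structure-area minima are `NA`.
#'
#' @param map A [field_map()].
#' @param layout Optional [build_grid()] layout; defaults to the one the
#'   map was built with.
#' @return `summarize_structure_area()`: named numeric vector of minima.
#'   `summarize_flume_area()`: list with named vectors `mean` and `sd`, and
#'   the cell count `n`.
#' @export
summarize_structure_area <- function(map, layout = attr(map, "layout")) {
  stopifnot(inherits(map, "field_map"))
  wake <- map[map$area_class == "structure_wake", , drop = FALSE]
  expected <- sum(layout$area_class == "structure_wake")
  if (nrow(wake) < expected) {
    miss <- setdiff(paste(layout$grid_row[layout$area_class == "structure_wake"],
                          layout$grid_col[layout$area_class == "structure_wake"]),
                    paste(wake$grid_row, wake$grid_col))
    stop_invalid("incomplete map; missing wake cell(s): ", paste(miss, collapse = "; "))
  }
  if (nrow(wake) == 0)
    return(stats::setNames(rep(NA_real_, length(map_variables)), map_variables))
  vapply(map_variables, function(v) min(wake[[v]]), numeric(1))
}

#' @rdname summarize_structure_area
#' @export
summarize_flume_area <- function(map, layout = attr(map, "layout")) {
  stopifnot(inherits(map, "field_map"))
  flume <- map[map$area_class == "flume", , drop = FALSE]
  expected <- sum(layout$area_class == "flume")
  if (nrow(flume) < expected)
    stop_invalid("incomplete map; flume cells missing")
  list(mean = vapply(map_variables, function(v) mean(flume[[v]]), numeric(1)),
       sd = vapply(map_variables, function(v) stats::sd(flume[[v]]), numeric(1)),
       n = nrow(flume))
}

#' Tabulate area summaries across treatments
#'
#' Builds the standard per-treatment summary table: structure-area minima
#' and flume-area mean +/- SD of front pressure, front fluctuations and log
#' asymmetry.
#'
#' @param maps Named list of [field_map()] objects (names = treatments).
#' @return Data frame, one row per treatment.
#' @export
pressure_summary <- function(maps) {
  rows <- lapply(names(maps), function(tr) {
    mn <- summarize_structure_area(maps[[tr]])
    fl <- summarize_flume_area(maps[[tr]])
    data.frame(treatment = tr,
               min_front_pressure = mn[["p_front_mean"]],
               min_front_fluct = mn[["p_front_fluct"]],
               min_asym_log = mn[["p_asym_log"]],
               flume_front_pressure_mean = fl$mean[["p_front_mean"]],
               flume_front_pressure_sd = fl$sd[["p_front_mean"]],
               flume_front_fluct_mean = fl$mean[["p_front_fluct"]],
               flume_front_fluct_sd = fl$sd[["p_front_fluct"]],
               flume_asym_log_mean = fl$mean[["p_asym_log"]],
               flume_asym_log_sd = fl$sd[["p_asym_log"]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export a field map as gridded CSV
#'
#' Writes the per-cell variables in the canonical gridded schema
#' (`grid_row`, `grid_col`, `zone`, `area_class`, variables, `treatment`).
#' Use [plot.field_map()] for a heat-map rendering.
#'
#' @param map A [field_map()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
export_maps <- function(map, path) {
  stopifnot(inherits(map, "field_map"))
  df <- as.data.frame(map)
  df$treatment <- attr(map, "treatment")
  df <- df[, c("grid_row", "grid_col", "zone", "area_class",
               "p_front_mean", "p_front_fluct", "p_asym", "p_asym_log",
               "treatment")]
  write_results(df, path)
  invisible(path)
}

#' Heat-map rendering of a field map
#'
#' Draws the spatial distribution of front pressure, front fluctuations and
#' log asymmetry over the measurement grid, flow from top (upstream) to
#' bottom; structure cells are outlined.
#'
#' @param x A [field_map()].
#' @param variables Which variables to draw.
#' @param ... Unused.
#' @export
plot.field_map <- function(x, variables = map_variables, ...) {
  layout_obj <- attr(x, "layout")
  nr <- attr(layout_obj, "n_rows"); nc <- attr(layout_obj, "n_cols")
  old <- graphics::par(mfrow = c(1, length(variables)), mar = c(2, 2, 3, 1))
  on.exit(graphics::par(old))
  for (v in variables) {
    z <- matrix(NA_real_, nr, nc)
    z[cbind(x$grid_row, x$grid_col)] <- x[[v]]
    graphics::image(seq_len(nc), seq_len(nr), t(z[nr:1, , drop = FALSE]),
                    col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE),
                    xlab = "", ylab = "", axes = FALSE,
                    main = paste0(attr(x, "treatment"), ": ", v))
    st <- attr(layout_obj, "structures")
    if (nrow(st))
      graphics::points(st$col, nr - st$row + 1, pch = 2, cex = 1.4)
  }
  invisible(x)
}
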