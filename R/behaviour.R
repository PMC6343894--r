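#' Behaviour metric sets of the ethogram
#'
#' The ten behaviour metrics fall into two categories: structure use
#' (`Iref`/`Gref` sheltering behind a structure, `Imiddle`/`Gmiddle`
#' passage on the long mid-channel side, `Iwall`/`Gwall` passage on the
#' short wall side) and swimming activity (`Isprint`/`Gsprint` burst
#' swimming, `Idrift`/`Gdrift` passive downstream displacement). `I` marks
#' an individual fish, `G` a group of two or more.
#'
#' @return List with character vectors `structure`, `activity` and `all`.
#' @export
behaviour_metric_sets <- function() {
  structure_set <- c("Iref", "Gref", "Imiddle", "Gmiddle", "Iwall", "Gwall")
  activity_set <- c("Isprint", "Gsprint", "Idrift", "Gdrift")
  list(structure = structure_set,
       activity = activity_set,
       all = c(structure_set, activity_set))
}

event_columns <- c("treatment", "replicate", "metric",
                   "start_time_s", "start_zone", "group_size")

#' Validate a coded behaviour-event log
#'
#' Checks every record of a manually coded event log against the ethogram
#' rules: known metric and treatment; replicate within the design; start
#' time within the event duration; start zone one of `C1`..`C5`; group size
#' 1 for `I` metrics and 2..school size for `G` metrics; and no
#' structure-use metrics under the structure-free `R0` configuration.
#' Violations are reported together with the offending row indices.
#'
#' @param events Data frame in the event-log schema (`treatment`,
#'   `replicate`, `metric`, `start_time_s`, `start_zone`, `group_size`).
#' @param design An [experiment_design()].
#' @return The validated log, invisibly unchanged.
#' @export
validate_events <- function(events, design) {
  stopifnot(inherits(design, "experiment_design"))
  miss <- setdiff(event_columns, names(events))
  if (length(miss))
    stop_invalid("event log lacks column(s): ", paste(miss, collapse = ", "))
  sets <- behaviour_metric_sets()
  problems <- character(0)
  flag <- function(bad, msg) {
    if (any(bad))
      problems <<- c(problems, paste0(msg, " (rows ",
                                      paste(which(bad), collapse = ", "), ")"))
  }
  flag(!events$metric %in% sets$all, "unknown behaviour metric")
  flag(!events$treatment %in% design$treatments, "treatment not in design")
  flag(!events$replicate %in% seq_len(design$replicates), "replicate not in design")
  flag(!is.na(events$start_time_s) &
         (events$start_time_s < 0 | events$start_time_s > design$event_duration),
       "start time outside the flow event")
  flag(!events$start_zone %in% paste0("C", 1:5), "invalid start zone")
  is_I <- grepl("^I", events$metric)
  flag(is_I & events$group_size != 1, "individual metric with group size != 1")
  flag(!is_I & (events$group_size < 2 | events$group_size > design$school_size),
       "group metric with group size outside 2..school size")
  flag(treatment_configuration(events$treatment) == "R0" &
         events$metric %in% sets$structure,
       "structure-use metric recorded under R0 (no structures present)")
  if (length(problems))
    stop_invalid("invalid behaviour events:\n  ",
                 paste(problems, collapse = "\n  "))
  invisible(events)
}

#' Assign an observation zone to a behaviour start position
#'
#' A behaviour occurrence belongs to the zone where it *began*, regardless
#' of where it ended. Zones are streamwise bands delimited by `boundaries`
#' (ascending, in m from the upstream end). A start exactly on a boundary
#' is assigned to the upstream (lower-indexed) zone.
#'
#' @param start_position Streamwise start position(s) in m.
#' @param boundaries Ascending numeric vector of zone edges, length
#'   `n_zones + 1` (first = upstream end, last = downstream end).
#' @return Zone label(s) `"C1"`, `"C2"`, ...
#' @examples
#' assign_zone(c(0, 1.3, 2.6), seq(0, 6.5, by = 1.3)) # C1 C1 C2
#' @export
assign_zone <- function(start_position, boundaries) {
  if (!is.numeric(boundaries) || length(boundaries) < 2L ||
      is.unsorted(boundaries, strictly = TRUE))
    stop_invalid("'boundaries' must be strictly ascending with >= 2 values")
  if (any(start_position < boundaries[1] | start_position > boundaries[length(boundaries)]))
    stop_invalid("start position outside the flume")
  # interval (b_i, b_{i+1}]: boundary points fall to the upstream zone
  idx <- findInterval(start_position, boundaries, left.open = TRUE)
  idx[start_position == boundaries[1]] <- 1L
  paste0("C", idx)
}

#' Tabulate behaviour frequencies
#'
#' Counts occurrences of each behaviour metric per treatment x replicate
#' (the absolute frequency over the flow event), optionally split by start
#' zone. Missing combinations are filled with 0, except structure-use
#' metrics under `R0`, which are absent by design and coded `NA`.
#'
#' @param events A validated event log (see [validate_events()]).
#' @param design An [experiment_design()].
#' @param by_zone If `TRUE`, keep one row per zone as well; zone marginals
#'   then sum to the per-replicate totals.
#' @return A `frequency_table` data frame (`treatment`, `replicate`,
#'   `metric`, optionally `zone`, `count`).
#' @export
tabulate_frequencies <- function(events, design, by_zone = FALSE) {
  validate_events(events, design)
  sets <- behaviour_metric_sets()
  grid <- if (by_zone) {
    expand.grid(zone = paste0("C", 1:5), metric = sets$all,
                replicate = seq_len(design$replicates),
                treatment = design$treatments,
                stringsAsFactors = FALSE)
  } else {
    expand.grid(metric = sets$all, replicate = seq_len(design$replicates),
                treatment = design$treatments, stringsAsFactors = FALSE)
  }
  keygrid <- if (by_zone)
    paste(grid$treatment, grid$replicate, grid$metric, grid$zone)
  else paste(grid$treatment, grid$replicate, grid$metric)
  keyev <- if (by_zone)
    paste(events$treatment, events$replicate, events$metric, events$start_zone)
  else paste(events$treatment, events$replicate, events$metric)
  counts <- as.integer(table(factor(keyev, levels = keygrid)))
  absent <- treatment_configuration(grid$treatment) == "R0" &
    grid$metric %in% sets$structure
  counts[absent] <- NA_integer_
  cols <- c("treatment", "replicate", "metric", if (by_zone) "zone")
  out <- cbind(grid[, cols, drop = FALSE], count = counts)
  rownames(out) <- NULL
  class(out) <- c("frequency_table", "data.frame")
  out
}

#' Expand a frequency table back into a minimal event log
#'
#' Inverse of [tabulate_frequencies()] up to event detail: each counted
#' occurrence becomes one synthetic event (times spread uniformly over the
#' flow event, start zone `C1` unless the table carries zones, group size 1
#' for `I` metrics and 2 for `G` metrics). Re-tabulating the result
#' reproduces the original counts exactly.
#'
#' @param freq A `frequency_table`.
#' @param design An [experiment_design()].
#' @return An event-log data frame.
#' @export
events_from_frequencies <- function(freq, design) {
  stopifnot(inherits(design, "experiment_design"))
  keep <- !is.na(freq$count) & freq$count > 0
  f <- freq[keep, , drop = FALSE]
  idx <- rep(seq_len(nrow(f)), f$count)
  within_idx <- sequence(f$count)
  out <- data.frame(
    treatment = f$treatment[idx],
    replicate = f$replicate[idx],
    metric = f$metric[idx],
    start_time_s = design$event_duration * (within_idx - 0.5) / f$count[idx],
    start_zone = if ("zone" %in% names(f)) f$zone[idx] else "C1",
    group_size = ifelse(grepl("^I", f$metric[idx]), 1L, 2L),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Aggregate a frequency table into a CA contingency table
#'
#' Builds the contingency table for correspondence analysis: rows are
#' treatments (replicates summed) or individual replicates, columns are the
#' metrics of the chosen set. The structure-use set uses the 6 structure
#' metrics over the 4 treatments with structures (`R0` excluded, since its
#' structure metrics are absent); the swimming-activity set uses the 4
#' activity metrics over all 5 treatments. All-zero rows or columns are
#' flagged via the `zero_margins` attribute (correspondence analysis cannot
#' use them).
#'
#' @param freq A `frequency_table` (without zone split).
#' @param set `"structure"` or `"activity"`.
#' @param level `"treatment"` (sum replicates; default) or `"replicate"`.
#' @return Integer matrix with treatments (or treatment_replicate) as rows
#'   and metrics as columns.
#' @export
aggregate_for_ca <- function(freq, set = c("structure", "activity"),
                             level = c("treatment", "replicate")) {
  set <- match.arg(set)
  level <- match.arg(level)
  sets <- behaviour_metric_sets()
  metrics <- sets[[set]]
  f <- freq[freq$metric %in% metrics, , drop = FALSE]
  if (set == "structure")
    f <- f[treatment_configuration(f$treatment) != "R0", , drop = FALSE]
  if (nrow(f) == 0) stop_invalid("no rows left to aggregate")
  if (anyNA(f$count)) stop_invalid("NA counts in a non-absent combination")
  rowkey <- if (level == "treatment") f$treatment
            else paste(f$treatment, f$replicate, sep = "_")
  tab <- tapply(f$count, list(factor(rowkey, levels = unique(rowkey)),
                              factor(f$metric, levels = metrics)), sum)
  tab[is.na(tab)] <- 0
  tab <- matrix(as.numeric(tab), nrow(tab), ncol(tab), dimnames = dimnames(tab))
  zero_rows <- rownames(tab)[rowSums(tab) == 0]
  zero_cols <- colnames(tab)[colSums(tab) == 0]
  attr(tab, "zero_margins") <- list(rows = zero_rows, cols = zero_cols)
  tab
}
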