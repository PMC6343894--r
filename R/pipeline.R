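#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end driver reproducing the study's analysis chain on data from
#' the synthetic generators: (1) per-treatment LLP pressure fields on the
#' measurement grid, summarised into structure-area minima and flume-area
#' mean +/- SD; (2) behaviour-metric counts and physiology samples; (3) the
#' inference battery — Kruskal-Wallis with Nemenyi contrasts for glucose,
#' lactate and each behaviour metric (structure-use metrics compared over
#' the four structure treatments, activity metrics over all five),
#' correspondence analysis of the structure-use and activity contingency
#' tables, and two-way PERMANOVA (Euclidean distance, flow event then
#' configuration, sequential SS).
#'
#' @param seed Integer seed driving every random component.
#' @param config Configuration list as from [default_config()] or
#'   [read_config()].
#' @param verbose Log stage-by-stage progress via `message()`.
#' @return An object of class `llp_pipeline`: list with elements `design`,
#'   `flow`, `maps`, `pressure_summary`, `counts`, `physiology`, `stats`
#'   (named list of fitted objects), `tidy` (flat data frame of all test
#'   results), `seed`, `config`.
#' @export
run_pipeline <- function(seed, config = default_config(), verbose = FALSE) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  seed <- as.integer(seed)
  llp_log("config hash ", config_hash(config), ", seed ", seed, verbose = verbose)

  design <- do.call(experiment_design, config$design)
  flow <- do.call(flow_event, config$flow)
  effects <- effect_spec()
  mode <- config$asymmetry_mode

  # --- hydrodynamic fields -------------------------------------------------
  trace_cfg <- config$trace
  trace_cfg$vortex_scale <- unlist(trace_cfg$vortex_scale)
  maps <- list()
  for (tr in design$treatments) {
    layout <- build_grid(configuration = treatment_configuration(tr),
                         n_rows = config$grid$n_rows, n_cols = config$grid$n_cols,
                         flume_width = config$grid$flume_width,
                         reach_length = config$grid$reach_length,
                         wake_length = config$grid$wake_length)
    traces <- do.call(generate_field_scenario,
                      c(list(layout = layout, treatment = tr,
                             seed = seed + 17L * match(tr, design$treatments),
                             flow = flow),
                        trace_cfg))
    maps[[tr]] <- summarize_field(traces, layout, mode = mode)
    llp_log("field ", tr, ": ", length(traces), " cells", verbose = verbose)
  }
  press <- pressure_summary(maps)

  # --- observations --------------------------------------------------------
  counts <- generate_behaviour_counts(design, effects, seed = seed + 1000L)
  phys <- generate_physiology(design, effects, seed = seed + 2000L)
  llp_log("observations: ", nrow(counts), " count rows, ", nrow(phys),
          " fish", verbose = verbose)

  # --- inference -----------------------------------------------------------
  sets <- behaviour_metric_sets()
  stats_out <- list(
    glucose_kw = kruskal_wallis(phys$glucose, phys$treatment),
    glucose_nemenyi = nemenyi_pairwise(phys$glucose, phys$treatment),
    lactate_kw = kruskal_wallis(phys$lactate, phys$treatment),
    lactate_nemenyi = nemenyi_pairwise(phys$lactate, phys$treatment)
  )
  for (m in sets$all) {
    sub <- counts[counts$metric == m & !is.na(counts$count), , drop = FALSE]
    stats_out[[paste0(m, "_kw")]] <- kruskal_wallis(sub$count, sub$treatment)
  }
  ca_structure_tab <- aggregate_for_ca(counts, "structure", "treatment")
  ca_activity_tab <- aggregate_for_ca(counts, "activity", "treatment")
  stats_out$ca_structure <- correspondence_analysis(ca_structure_tab)
  stats_out$ca_activity <- correspondence_analysis(ca_activity_tab)

  perm_inputs <- permanova_inputs(counts)
  stats_out$permanova_structure <- permanova(
    perm_inputs$structure$response, perm_inputs$structure$factors,
    n_permutations = config$n_permutations, seed = seed + 3000L)
  stats_out$permanova_activity <- permanova(
    perm_inputs$activity$response, perm_inputs$activity$factors,
    n_permutations = config$n_permutations, seed = seed + 4000L)

  tidy <- do.call(rbind, c(
    list(tidy_stat(stats_out$glucose_kw, "glucose"),
         tidy_stat(stats_out$glucose_nemenyi, "glucose"),
         tidy_stat(stats_out$lactate_kw, "lactate"),
         tidy_stat(stats_out$lactate_nemenyi, "lactate")),
    lapply(sets$all, function(m) tidy_stat(stats_out[[paste0(m, "_kw")]], m)),
    list(tidy_stat(stats_out$permanova_structure, "structure_use"),
         tidy_stat(stats_out$permanova_activity, "swimming_activity"))
  ))

  structure(
    list(design = design, flow = flow, maps = maps, pressure_summary = press,
         counts = counts, physiology = phys, stats = stats_out, tidy = tidy,
         seed = seed, config = config),
    class = "llp_pipeline"
  )
}

#' Assemble PERMANOVA response matrices from a frequency table
#'
#' Builds the two replicate-level multivariate responses of the analysis:
#' the structure-use matrix (replicates of the four structure treatments x
#' 6 metrics) and the swimming-activity matrix (all replicates x 4
#' metrics), each with crossed factors `event` (HP/BF) and `configuration`.
#'
#' @param counts A `frequency_table`.
#' @return List of two lists (`structure`, `activity`), each with a
#'   `response` matrix and a `factors` data frame.
#' @export
permanova_inputs <- function(counts) {
  build <- function(set) {
    tab <- aggregate_for_ca(counts, set, "replicate")
    labels <- sub("_[0-9]+$", "", rownames(tab))
    list(response = tab,
         factors = data.frame(event = treatment_event(labels),
                              configuration = treatment_configuration(labels)))
  }
  list(structure = build("structure"), activity = build("activity"))
}

#' @export
print.llp_pipeline <- function(x, ...) {
  cat("Hydropeaking flume analysis pipeline (seed ", x$seed, ")\n\n", sep = "")
  print(x$design)
  cat("\n")
  print(x$flow)
  cat("\nPressure field summary (Pa; asymmetry log Pa^2):\n")
  ps <- x$pressure_summary
  num <- vapply(ps, is.numeric, logical(1))
  ps[num] <- lapply(ps[num], report_round, digits = x$config$rounding$pressure)
  print(ps, row.names = FALSE)
  cat("\nKey tests:\n")
  for (nm in c("glucose_kw", "lactate_kw", "Iref_kw")) {
    s <- x$stats[[nm]]
    cat(sprintf("  %-12s chi-squared(%d) = %.3f, p = %.3f\n",
                sub("_kw", "", nm), s$df, s$statistic, s$p_value))
  }
  for (nm in c("ca_structure", "ca_activity")) {
    s <- x$stats[[nm]]
    cat(sprintf("  %-12s first two axes explain %.1f%% of inertia\n",
                nm, 100 * s$cumulative[min(2, length(s$cumulative))]))
  }
  for (nm in c("permanova_structure", "permanova_activity")) {
    s <- x$stats[[nm]]$terms
    cat(sprintf("  %-20s event F = %.3f, p = %.3f\n",
                nm, s$F[1], s$p_value[1]))
  }
  invisible(x)
}

#' Export pipeline outputs as CSV files
#'
#' Writes the pressure summary, per-treatment gridded maps, behaviour
#' counts, physiology records and the tidy statistics table into a
#' directory.
#'
#' @param result An `llp_pipeline` object.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_pipeline <- function(result, dir) {
  stopifnot(inherits(result, "llp_pipeline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_results(result$pressure_summary, file.path(dir, "pressure_summary.csv"))
  for (tr in names(result$maps))
    export_maps(result$maps[[tr]], file.path(dir, paste0("map_", tr, ".csv")))
  write_results(result$counts, file.path(dir, "behaviour_counts.csv"))
  write_results(result$physiology, file.path(dir, "physiology.csv"))
  write_results(result$tidy, file.path(dir, "stats.csv"))
  invisible(dir)
}
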