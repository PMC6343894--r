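# Canonical interchange format is delimited text: CSV, UTF-8, '.' decimal.
# Column schemas mirror the derived-variable and raw-trace layouts.

llp_schemas <- list(
  summary = c("treatment", "grid_row", "grid_col",
              "p_front_mean", "p_front_fluct", "p_asym", "p_asym_log"),
  raw = c("treatment", "grid_row", "grid_col", "time_s",
          paste0("p", 1:6), "p_abs")
)

#' Write a results table to CSV
#'
#' Delimited-text writer used by every pipeline stage: UTF-8, header, `.`
#' decimal separator, fixed column order as given, full double precision so
#' tables round-trip through [read_llp_table()] and friends unchanged.
#'
#' @param results A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (!is.data.frame(results)) stop_invalid("'results' must be a data frame")
  utils::write.csv(results, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Read a CSV and coerce declared numeric columns, reporting the first
# offending row when a value does not parse.
read_checked_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_invalid("schema error: missing column(s) ", paste(miss, collapse = ", "),
                 " in ", path)
  for (col in intersect(numeric_cols, names(df))) {
    raw <- df[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !(is.na(raw) | raw == "" | raw == "NA"))
    if (length(bad))
      stop_invalid("parse error: non-numeric value ", dQuote(raw[bad[1]]),
                   " in column '", col, "' at row ", bad[1])
    df[[col]] <- val
  }
  df
}

#' Read an LLP table (per-cell summaries or raw samples)
#'
#' Ingests the canonical CSV layouts for probe data. The `schema` argument
#' declares whether rows are per-cell derived summaries (`treatment`,
#' `grid_row`, `grid_col`, `p_front_mean`, `p_front_fluct`, `p_asym`,
#' `p_asym_log`) or raw samples (`treatment`, `grid_row`, `grid_col`,
#' `time_s`, `p1`..`p6`, `p_abs`). Records are validated: missing columns
#' raise a schema error naming the column; non-numeric pressure values
#' raise a parse error with the row index. An empty data section (header
#' only) returns an empty table without error.
#'
#' @param path CSV file path.
#' @param schema `"summary"` or `"raw"`.
#' @return Data frame keyed by (`treatment`, `grid_row`, `grid_col`); unit
#'   metadata (Pa, seconds) is attached as the `units` attribute.
#' @export
read_llp_table <- function(path, schema = c("summary", "raw")) {
  schema <- match.arg(schema)
  cols <- llp_schemas[[schema]]
  df <- read_checked_csv(path, cols, setdiff(cols, "treatment"))
  df <- df[, cols, drop = FALSE]
  attr(df, "units") <- if (schema == "summary") {
    c(p_front_mean = "Pa", p_front_fluct = "Pa", p_asym = "Pa^2",
      p_asym_log = "log Pa^2")
  } else {
    c(time_s = "s", pressure = "Pa")
  }
  attr(df, "schema") <- schema
  df
}

#' Read fish observation tables (physiology and behaviour counts)
#'
#' `read_physiology_table()` reads per-fish records (`fish_id`,
#' `treatment`, `replicate`, `glucose` in mg/dl, `lactate` in mM),
#' rejecting duplicate fish ids and non-positive concentrations.
#' `read_frequency_table()` reads per-replicate behaviour counts
#' (`treatment`, `replicate`, `metric`, `count`), rejecting negative or
#' non-integer counts (`NA` marks combinations absent by design).
#' `read_observation_table()` reads both and returns them as a list.
#'
#' @param path CSV file path.
#' @param physiology_path,counts_path Paths of the two tables.
#' @return `read_observation_table()`: list with elements `physiology` and
#'   `frequencies`.
#' @export
read_observation_table <- function(physiology_path, counts_path) {
  list(physiology = read_physiology_table(physiology_path),
       frequencies = read_frequency_table(counts_path))
}

#' @rdname read_observation_table
#' @export
read_physiology_table <- function(path) {
  cols <- c("fish_id", "treatment", "replicate", "glucose", "lactate")
  df <- read_checked_csv(path, cols, c("replicate", "glucose", "lactate"))
  df <- df[, cols, drop = FALSE]
  if (nrow(df) == 0) return(df)
  if (anyDuplicated(df$fish_id))
    stop_invalid("validation error: duplicate fish id(s): ",
                 paste(unique(df$fish_id[duplicated(df$fish_id)]), collapse = ", "))
  bad <- which(is.na(df$glucose) | is.na(df$lactate) |
                 df$glucose <= 0 | df$lactate <= 0)
  if (length(bad))
    stop_invalid("validation error: non-positive or missing concentration at row ",
                 bad[1])
  if (!all(grepl("^R[0-2](HP|BF)$", df$treatment)))
    stop_invalid("validation error: malformed treatment label")
  df$replicate <- as.integer(df$replicate)
  df
}

#' @rdname read_observation_table
#' @export
read_frequency_table <- function(path) {
  cols <- c("treatment", "replicate", "metric", "count")
  df <- read_checked_csv(path, cols, c("replicate", "count"))
  df <- df[, intersect(c(cols, "zone"), names(df)), drop = FALSE]
  if (nrow(df) == 0) {
    class(df) <- c("frequency_table", "data.frame")
    return(df)
  }
  bad <- which(!is.na(df$count) & (df$count < 0 | df$count != round(df$count)))
  if (length(bad))
    stop_invalid("validation error: negative or non-integer count at row ", bad[1])
  known <- behaviour_metric_sets()$all
  if (!all(df$metric %in% known))
    stop_invalid("validation error: unknown behaviour metric ",
                 paste(setdiff(unique(df$metric), known), collapse = ", "))
  df$replicate <- as.integer(df$replicate)
  df$count <- as.integer(df$count)
  class(df) <- c("frequency_table", "data.frame")
  df
}
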