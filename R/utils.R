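# Internal helpers shared across modules.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so seeded generators do not perturb the global stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Rounding used only at the reporting layer; raw values are retained
# everywhere internally.
report_round <- function(x, digits) round(x, digits)

is_count <- function(x) {
  is.numeric(x) & is.finite(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

`%||%` <- function(a, b) if (is.null(a)) b else a

llp_log <- function(..., verbose = getOption("hydrollp.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[hydrollp] ", ...)
  invisible(NULL)
}

# Tiny stable hash of a config list for logging provenance (not cryptographic).
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_along(utf8ToInt(txt))) %% 0xFFFFFFFF)
}
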