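#' @keywords internal
"_PACKAGE"

# Condition helpers ---------------------------------------------------------
# Two error families map onto the CLI exit codes: validation errors (bad
# inputs, schema violations, capacity) -> exit 2; degenerate-data errors
# (zero variance, insufficient controls) -> exit 3.

stop_validation <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("lumiscreen_validation_error", "lumiscreen_error")))
}

stop_degenerate <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("lumiscreen_degenerate_error", "lumiscreen_error")))
}

# Run seeded code without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_validation("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_validation(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop_validation(name, " must be a single positive number")
  }
  as.numeric(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_validation(name, " must lie in [0, 1]")
  }
  as.numeric(x)
}

# Deterministic hash of a config list, recorded in every output sidecar.
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(json), tmp, sep = "")
  unname(tools::md5sum(tmp))
}

# Structured stage logging to stderr; results go to files only.
log_stage <- function(stage, ...) {
  message(sprintf("[lumiscreen] %s: %s", stage, paste0(...)))
}
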