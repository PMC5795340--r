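#' @title Internal helpers
#' @noRd
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# POSIXct (UTC) coercion with validation.
as_utc <- function(x, what = "time") {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (is.character(x)) {
    out <- suppressWarnings(as.POSIXct(x, tz = "UTC",
      tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                     "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")))
    if (anyNA(out)) stop(sprintf("cannot parse %s as ISO-8601 UTC: %s",
                                 what, paste(head(x[is.na(out)], 3L), collapse = ", ")),
                         call. = FALSE)
    return(out)
  }
  if (is.numeric(x)) return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  stop(sprintf("%s must be POSIXct, ISO-8601 string or numeric", what), call. = FALSE)
}

# Midnight (UTC) of the day containing `time`.
midnight_of <- function(time) {
  time <- as_utc(time)
  as.POSIXct(floor(as.numeric(time) / 86400) * 86400, origin = "1970-01-01", tz = "UTC")
}

format_utc <- function(x) format(as_utc(x), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

stop_invariant <- function(invariant, ...) {
  stop(sprintf("invariant violated [%s]: %s", invariant, sprintf(...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
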