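#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG seed without clobbering the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

## Day of year with January 1st = day 0.
doy0 <- function(timestamp) {
  as.POSIXlt(timestamp, tz = "UTC")$yday
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
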