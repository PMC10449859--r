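## internal helpers shared across modules

DAYS_PER_YEAR <- 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg),
       call. = FALSE)
}

stop_data <- function(msg) stop(sprintf("data error: %s", msg), call. = FALSE)

## clock hour of day in [0, 24) for POSIXct (UTC) or numeric hours
clock_hours <- function(time) {
  if (inherits(time, "POSIXct")) {
    (as.numeric(time) / 3600) %% 24
  } else {
    as.numeric(time) %% 24
  }
}

## absolute time in hours (monotone), POSIXct or numeric
abs_hours <- function(time) {
  if (inherits(time, "POSIXct")) as.numeric(time) / 3600 else as.numeric(time)
}

years_between <- function(from, to) as.numeric(to - from) / DAYS_PER_YEAR

## deterministic child seed so independent stages don't share streams
child_seed <- function(seed, k) (seed * 69091L + k * 1009L) %% .Machine$integer.max
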