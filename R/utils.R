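#' Round half away from zero
#'
#' Base \code{round()} rounds half to even ("banker's rounding"); all
#' percentages, multipliers and person counts in this package follow the
#' conventional half-up rule instead (0.5 rounds away from zero), which is
#' the convention that reproduces the published summary figures.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(0.45, 1)   # 0.5
#' round_half_up(3907.2, 0) # 3907
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a field name, used by config validators so the offending
# field is always part of the message
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# local clock time of day in fractional hours, in the timestamp's own tz
local_hour <- function(timestamp) {
  lubridate::hour(timestamp) +
    lubridate::minute(timestamp) / 60 +
    lubridate::second(timestamp) / 3600
}

# empty canonical probe-log tibble (shared by simulator and reader)
empty_probe_log <- function(tz = "Asia/Tokyo") {
  tibble::tibble(
    timestamp = as.POSIXct(character(), tz = tz),
    device_id = character(),
    oui = character(),
    rssi = integer()
  )
}
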