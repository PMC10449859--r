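#' Convert raw wrist-sensor readings to degrees Celsius
#'
#' The on-device thermometer reports temperature in arbitrary sensor units
#' \code{X}; the calibrated temperature in degrees Celsius is the linear
#' rescaling \code{T = (500 * X - 2550) / 256}.  The map is strictly
#' increasing and exactly invertible (see \code{\link{convert_celsius_to_raw}}).
#'
#' @param raw numeric vector of raw sensor readings.
#' @return numeric vector of temperatures in degrees Celsius.
#' @seealso \code{\link{convert_celsius_to_raw}}
#' @examples
#' convert_raw_to_celsius(c(5.1, 10.22))  # 0 and 10 degrees C
#' @export
convert_raw_to_celsius <- function(raw) {
  if (!is.numeric(raw)) stop_data("raw sensor values must be numeric")
  if (any(!is.finite(raw) & !is.na(raw)))
    stop_data("raw sensor values must be finite")
  (500 * raw - 2550) / 256
}

#' Convert degrees Celsius back to raw sensor units
#'
#' Exact inverse of \code{\link{convert_raw_to_celsius}}:
#' \code{X = (256 * T + 2550) / 500}.
#'
#' @param celsius numeric vector of temperatures in degrees Celsius.
#' @return numeric vector of raw sensor units.
#' @export
convert_celsius_to_raw <- function(celsius) {
  if (!is.numeric(celsius)) stop_data("temperatures must be numeric")
  if (any(!is.finite(celsius) & !is.na(celsius)))
    stop_data("temperatures must be finite")
  (256 * celsius + 2550) / 500
}

#' Mask non-wear epochs in a temperature series
#'
#' Temperature readings taken while the device is off the wrist are
#' non-physiological.  Epochs flagged \code{wear = FALSE} have their
#' temperature set to \code{NA} (a missing marker, never a fill value).
#' Participants whose remaining wear time falls below the minimum-data rule
#' (at least \code{min_hours} hours of wear epochs spanning at least
#' \code{min_days} distinct calendar days) are flagged insufficient and
#' should not be fit.
#'
#' @param series data frame with columns \code{participant_id},
#'   \code{timestamp} (POSIXct or numeric hours), \code{temp_c} and logical
#'   \code{wear}.
#' @param epoch_minutes epoch length in minutes, used to convert epoch counts
#'   to hours of wear.
#' @param min_hours minimum total hours of wear epochs per participant.
#' @param min_days minimum number of distinct calendar days with wear data.
#' @return the series with masked temperatures set to \code{NA}, plus an
#'   attribute \code{"wear_summary"}: one row per participant with the number
#'   of valid epochs, the wear fraction and an \code{insufficient} flag.
#' @export
mask_nonwear <- function(series, epoch_minutes = 5, min_hours = 72,
                         min_days = 3) {
  if (!all(c("participant_id", "timestamp", "temp_c", "wear") %in%
           names(series)))
    stop_data("series must have participant_id, timestamp, temp_c, wear")
  wear <- as.logical(series$wear)
  out <- series
  out$temp_c[!wear] <- NA_real_
  if ("raw" %in% names(out)) out$raw[!wear] <- NA_real_

  day_id <- floor(abs_hours(series$timestamp) / 24)
  pid <- series$participant_id
  n_total <- tapply(wear, pid, length)
  n_valid <- tapply(wear, pid, sum)
  n_days <- tapply(day_id[wear], factor(pid[wear], levels = names(n_total)),
                   function(d) length(unique(d)))
  n_days[is.na(n_days)] <- 0L
  hours_valid <- n_valid * epoch_minutes / 60
  summary <- data.frame(
    participant_id = names(n_total),
    n_epochs = as.integer(n_total),
    n_valid = as.integer(n_valid),
    wear_fraction = as.numeric(n_valid / n_total),
    hours_valid = as.numeric(hours_valid),
    n_days = as.integer(n_days),
    insufficient = as.numeric(hours_valid) < min_hours |
      as.integer(n_days) < min_days,
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  attr(out, "wear_summary") <- summary
  out
}

#' Amplitude quality-control filter
#'
#' Cosinor amplitudes above \code{threshold} degrees Celsius are treated as
#' non-physiological and dropped from all downstream analysis.  The boundary
#' uses a strict inequality: an amplitude of exactly \code{threshold} is kept.
#'
#' @param amplitude numeric vector of cosinor amplitudes (degrees C, >= 0).
#' @param threshold drop threshold in degrees Celsius (default 10).
#' @return logical vector, \code{TRUE} = keep, \code{FALSE} = drop.
#' @export
qc_amplitude <- function(amplitude, threshold = 10) {
  if (any(amplitude < 0, na.rm = TRUE))
    stop("internal error: negative cosinor amplitude", call. = FALSE)
  !is.na(amplitude) & amplitude <= threshold
}

#' Normalize a temperature series to zero daily median
#'
#' For display of average traces, each participant-day is centred so that the
#' median over that day's wear epochs is 0 (midpoint interpolation for even
#' counts).  Days with no valid epoch are omitted from the output.
#'
#' @param series data frame as in \code{\link{mask_nonwear}}; masked epochs
#'   must already carry \code{NA}.
#' @return the series restricted to days with data, with an added column
#'   \code{temp_norm}.
#' @export
normalize_daily_median <- function(series) {
  day_id <- floor(abs_hours(series$timestamp) / 24)
  key <- paste(series$participant_id, day_id, sep = "\r")
  med <- tapply(series$temp_c, key, median, na.rm = TRUE)
  m <- as.numeric(med[key])
  out <- series
  out$temp_norm <- out$temp_c - m
  keep <- !is.na(m)   # drop days that are entirely missing
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
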