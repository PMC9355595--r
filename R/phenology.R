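# Dormancy phenology: chilling-hour accumulation, bud break rate, the
# endodormancy-release date, and the 2^-ddCt relative-expression utility.

#' Cumulative chilling hours
#'
#' Counts hourly temperature readings falling in the chilling band
#' (default `0 < T <= 7.2` degrees C: frozen hours are excluded, the upper
#' bound is inclusive) from `start` onward, and returns the running total
#' per timestamp. Missing hours are skipped, not interpolated; gaps larger
#' than one hour are reported in the `gaps` attribute.
#'
#' @param series data.frame with columns `timestamp` (POSIXct or coercible)
#'   and `temp_c`.
#' @param start start time (default: first timestamp).
#' @param lower,upper chilling band bounds in degrees C (default 0, 7.2).
#' @param lower_inclusive,upper_inclusive bound handling (default exclusive
#'   lower, inclusive upper).
#' @return data.frame `timestamp`, `temp_c`, `chilling`, `ch` (cumulative),
#'   with attribute `gaps` (data.frame of gap starts and lengths in hours).
#' @export
chilling_hours <- function(series, start = NULL, lower = 0, upper = 7.2,
                           lower_inclusive = FALSE, upper_inclusive = TRUE) {
  if (nrow(series) == 0) stop("empty temperature series", call. = FALSE)
  ts <- as.POSIXct(series$timestamp, tz = "UTC")
  ord <- order(ts)
  ts <- ts[ord]; temp <- series$temp_c[ord]
  if (anyDuplicated(ts)) stop("duplicate timestamps", call. = FALSE)
  if (is.null(start)) start <- ts[1]
  keep <- ts >= as.POSIXct(start, tz = "UTC")
  if (!any(keep)) stop("series does not cover the start date", call. = FALSE)
  ts <- ts[keep]; temp <- temp[keep]
  lo_ok <- if (lower_inclusive) temp >= lower else temp > lower
  hi_ok <- if (upper_inclusive) temp <= upper else temp < upper
  chill <- lo_ok & hi_ok
  out <- data.frame(timestamp = ts, temp_c = temp,
                    chilling = chill, ch = cumsum(chill))
  dt <- as.numeric(diff(ts), units = "hours")
  gap_idx <- which(dt > 1 + 1e-9)
  attr(out, "gaps") <- data.frame(after = ts[gap_idx], hours = dt[gap_idx])
  out
}

#' Bud break rate
#'
#' Percentage of floral buds that flushed after forcing incubation.
#'
#' @param flushed number of flushed buds.
#' @param total total buds observed.
#' @return percentage in `[0, 100]`.
#' @export
bud_break_rate <- function(flushed, total) {
  stopifnot(all(flushed >= 0), all(total >= flushed))
  100 * flushed / total
}

#' Endodormancy-release date
#'
#' The earliest observation date at which the bud break rate reaches the
#' release threshold (default 50\%): the date when half of the floral buds
#' are competent to flush under forcing conditions.
#'
#' @param observations data.frame with columns `date` and either `bbr`
#'   (percent) or `flushed` + `total`.
#' @param threshold release threshold in percent (default 50).
#' @return the release date, or `NA` if the threshold is never reached.
#' @export
endodormancy_release_date <- function(observations, threshold = 50) {
  if (nrow(observations) == 0) stop("no observations", call. = FALSE)
  bbr <- if ("bbr" %in% names(observations)) observations$bbr
         else bud_break_rate(observations$flushed, observations$total)
  dates <- as.Date(observations$date)
  ord <- order(dates)
  hit <- which(bbr[ord] >= threshold)
  if (length(hit) == 0) return(as.Date(NA))
  dates[ord][hit[1]]
}

#' Relative expression by the 2^-ddCt method
#'
#' `RE = 2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))`: the
#' expression of a target normalized to a reference gene and a calibrator
#' sample. The calibrator itself always evaluates to 1.
#'
#' @param ct_target,ct_ref Ct values of target and reference gene in the
#'   sample of interest.
#' @param ct_target_cal,ct_ref_cal Ct values in the calibrator sample.
#' @return relative expression (positive numeric).
#' @export
delta_delta_ct <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  ddct <- (ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}
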