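#' Growing degree hours for one day
#'
#' `GDH_i = sum over the 24 hours of max(HT_h - T_b, 0)`: hourly temperatures
#' below the base temperature contribute nothing (the hourly reading is
#' replaced by the base before subtracting).
#'
#' @param day_temps Exactly 24 hourly air temperatures, degC.
#' @param t_base Base temperature, degC (default 7).
#' @return Degree-hours for the day, nonnegative.
#' @export
daily_gdh <- function(day_temps, t_base = 7) {
  if (length(day_temps) != 24L || any(!is.finite(day_temps))) {
    stop("daily_gdh needs exactly 24 finite hourly temperatures", call. = FALSE)
  }
  sum(pmax(day_temps - t_base, 0))
}

#' Daily growing-degree-hour series from hourly temperatures
#'
#' Aggregates an hourly record into one GDH value per day. Days with fewer
#' or more than 24 readings are rejected rather than interpolated.
#'
#' @param temps Data frame with columns `timestamp_iso` (parseable as
#'   date-time, hourly) and `temp_C`, as read by [read_temperature_table()].
#' @param t_base Base temperature, degC.
#' @return Data frame with columns `date` (class `Date`) and `gdh`.
#' @export
gdh_series <- function(temps, t_base = 7) {
  temps <- as.data.frame(temps)
  stamps <- as.POSIXct(temps$timestamp_iso, tz = "UTC")
  if (any(is.na(stamps))) stop("unparseable timestamps in temperature table", call. = FALSE)
  day <- as.Date(stamps)
  counts <- table(day)
  bad <- names(counts)[counts != 24L]
  if (length(bad)) {
    stop("day(s) without exactly 24 hourly readings: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  agg <- tapply(temps$temp_C, day, daily_gdh, t_base = t_base)
  data.frame(date = as.Date(names(agg)), gdh = as.numeric(agg), row.names = NULL)
}

#' Cumulative growing degree days since full bloom
#'
#' `GDD_cum = sum over days from full bloom to D of GDH_i / 24`.
#'
#' @param daily Data frame with columns `date` and `gdh` (from
#'   [gdh_series()]).
#' @param fb Full-bloom date (`Date` or parseable string).
#' @param d Sampling date, `>= fb`.
#' @return Cumulative degree-days (degC day), nondecreasing in `d`.
#' @export
cumulative_gdd <- function(daily, fb, d) {
  fb <- as.Date(fb); d <- as.Date(d)
  if (d < fb) stop("sampling date precedes full bloom", call. = FALSE)
  wanted <- seq(fb, d, by = "day")
  daily <- as.data.frame(daily)
  idx <- match(wanted, as.Date(daily$date))
  if (any(is.na(idx))) {
    stop("temperature record does not cover every day from full bloom to the sampling date",
         call. = FALSE)
  }
  sum(daily$gdh[idx]) / 24
}

#' Retain only fully developed shoots
#'
#' Bourse shoots reach their final leaf number and total leaf area only after
#' a genotype-specific thermal time since full bloom; a bourse shoot is
#' retained iff its sampling GDD meets the threshold for its genotype.
#' Rosettes are fully preformed at bloom but senesce by harvest, so a rosette
#' is retained iff it was sampled before harvest. Other shoot types pass
#' through unchanged.
#'
#' @param shoots Data frame with columns `shoot_type`, `genotype`,
#'   `sampling_gdd` and (for rosettes) logical `at_harvest`.
#' @param thresholds Named vector of GDD thresholds per genotype; default the
#'   shipped 345 (AR) / 201 (FU) / 275 (RB).
#' @return The retained subset of `shoots`.
#' @export
full_development_filter <- function(shoots,
                                    thresholds = c(AR = 345, FU = 201, RB = 275)) {
  shoots <- as.data.frame(shoots)
  keep <- rep(TRUE, nrow(shoots))
  is_bs <- shoots$shoot_type == "BS"
  if (any(is_bs)) {
    g <- shoots$genotype[is_bs]
    if (any(!g %in% names(thresholds))) {
      stop("no GDD threshold configured for genotype(s): ",
           paste(unique(g[!g %in% names(thresholds)]), collapse = ", "),
           call. = FALSE)
    }
    keep[is_bs] <- shoots$sampling_gdd[is_bs] >= thresholds[g]
  }
  is_ro <- shoots$shoot_type == "RO"
  if (any(is_ro)) {
    if (is.null(shoots$at_harvest)) {
      stop("rosette records need an at_harvest flag", call. = FALSE)
    }
    keep[is_ro] <- !shoots$at_harvest[is_ro]
  }
  shoots[keep, , drop = FALSE]
}
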