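#' Calendar-day temperature thresholds (^80TX)
#'
#' For each calendar day of the season, pools TX over a centred window of
#' `window_days` days (drawing on out-of-season days when they exist in the
#' series) across all base-period years and takes the empirical percentile
#' with linear interpolation between order statistics
#' (`stats::quantile(type = 7)`). Leap day (Feb 29) pools are merged into
#' Feb 28.
#'
#' @param daily data frame with `date` and `tx` for one station.
#' @param percentile percentile as a fraction (default 0.80).
#' @param window_days centred window width in days, odd (default 31).
#' @param base_years years pooled over.
#' @param season_months months for which thresholds are produced.
#' @param min_pool minimum pooled values per calendar day (default 100).
#' @return object of class `event_thresholds`: list with
#'   `tx_thresholds` (named by "mm-dd"), `ozone_threshold`, `percentile`,
#'   `window_days`, `base_years`.
#' @export
tx_thresholds <- function(daily, percentile = 0.80, window_days = 31,
                          base_years, season_months = 4:9,
                          ozone_threshold = 100, min_pool = 100) {
  if (window_days %% 2 != 1)
    stop_otv("window_days must be odd", class = "configuration_error")
  dts <- as.Date(daily$date)
  keep <- date_year(dts) %in% base_years
  dts <- dts[keep]; tx <- daily$tx[keep]
  half <- (window_days - 1) / 2
  season_days <- unique(date_mmdd(season_dates(base_years, season_months)))
  # day-of-year on a fixed 365-day calendar, Feb 29 mapped onto Feb 28
  doy_of <- function(d) {
    mmdd <- date_mmdd(d)
    mmdd[mmdd == "02-29"] <- "02-28"
    as.integer(strftime(as.Date(paste0("2001-", mmdd)), "%j"))
  }
  doy <- doy_of(dts)
  thr <- vapply(season_days, function(md) {
    centre <- as.integer(strftime(as.Date(paste0("2001-", md)), "%j"))
    offs <- ((centre - half):(centre + half) - 1) %% 365 + 1
    pool <- tx[doy %in% offs & !is.na(tx)]
    if (length(pool) < min_pool)
      stop_otv("threshold pool for calendar day ", md, " has only ",
               length(pool), " values", class = "threshold_error")
    stats::quantile(pool, percentile, names = FALSE, type = 7)
  }, numeric(1))
  structure(list(tx_thresholds = thr, ozone_threshold = ozone_threshold,
                 percentile = percentile, window_days = window_days,
                 base_years = base_years, season_months = season_months),
            class = "event_thresholds")
}

#' Detect ozone, temperature, and compound o-t-events
#'
#' A day is an o-event when MDA8O3 strictly surpasses the ozone threshold
#' (WHO guideline, 100 ug/m3 by default), a t-event when TX strictly
#' surpasses the calendar-day ^80TX threshold, and a compound o-t-event
#' when both occur on the same day. Days with a missing input get missing
#' event indicators.
#'
#' @param daily data frame with `station_id`, `date`, `mda8o3`, `tx`.
#' @param thresholds an [tx_thresholds()] object.
#' @return data frame `station_id, date, o_event, t_event, ot_event`
#'   (integer 0/1 or NA), season days only.
#' @export
detect_events <- function(daily, thresholds) {
  stopifnot(inherits(thresholds, "event_thresholds"))
  dts <- as.Date(daily$date)
  in_season <- date_month(dts) %in% thresholds$season_months
  d <- daily[in_season, ]
  dts <- dts[in_season]
  mmdd <- date_mmdd(dts)
  mmdd[mmdd == "02-29"] <- "02-28"
  if (any(!mmdd %in% names(thresholds$tx_thresholds)))
    stop_otv("date outside threshold coverage", class = "domain_error")
  thr <- thresholds$tx_thresholds[mmdd]
  o <- ifelse(is.na(d$mda8o3), NA_integer_,
              as.integer(d$mda8o3 > thresholds$ozone_threshold))
  t_ <- ifelse(is.na(d$tx), NA_integer_, as.integer(d$tx > unname(thr)))
  ot <- ifelse(is.na(o) | is.na(t_), NA_integer_, as.integer(o == 1L & t_ == 1L))
  data.frame(station_id = d$station_id, date = dts,
             o_event = o, t_event = t_, ot_event = ot)
}

#' Summarize event counts
#'
#' @param events output of [detect_events()].
#' @return one-row data frame: counts of o-, t-, and o-t-event days over
#'   non-missing days, number of non-missing days, and the o-t-event
#'   fraction.
#' @export
event_summary <- function(events) {
  ok <- !is.na(events$ot_event)
  data.frame(o_days = sum(events$o_event == 1L, na.rm = TRUE),
             t_days = sum(events$t_event == 1L, na.rm = TRUE),
             ot_days = sum(events$ot_event == 1L, na.rm = TRUE),
             n_days = sum(ok),
             ot_fraction = if (any(ok))
               sum(events$ot_event[ok] == 1L) / sum(ok) else 0)
}
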