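#' Maximum daily 8-hour running mean ozone (MDA8O3)
#'
#' Computes the regulatory MDA8O3 metric from hourly ozone. An 8-hour
#' running mean is attached to its ending hour `h` in 1..24 and therefore
#' covers hours `h-7 .. h`, drawing on the previous calendar day for
#' `h < 8` (EU air-quality convention; configurable to interior-only
#' windows via `assign = "interior"`). A window is valid when at least
#' `min_valid_hours` of its 8 hours carry valid measurements, in which case
#' its mean is taken over the valid hours only. A day's MDA8O3 is the
#' maximum over its valid windows, provided at least `min_valid_windows`
#' windows are valid; otherwise the day is missing.
#'
#' @param hourly data frame with columns `station_id`, `timestamp`
#'   (POSIXct or string parseable as such), `value` (ug/m3), and `valid`
#'   (logical). Timestamps must be strictly increasing with one-hour
#'   spacing.
#' @param min_valid_windows minimum number of valid 8-h windows per day
#'   (default 18).
#' @param min_valid_hours minimum valid hours per 8-h window (default 6).
#' @param assign `"ending_hour"` (default; windows ending on hours 1..24
#'   belong to the day, reaching back into the previous day) or
#'   `"interior"` (only the 17 windows fully inside the day).
#' @return data frame with columns `station_id`, `date`, `mda8o3`
#'   (NA where the day has too few valid windows).
#' @export
compute_mda8 <- function(hourly, min_valid_windows = 18, min_valid_hours = 6,
                         assign = c("ending_hour", "interior")) {
  assign <- match.arg(assign)
  ts <- hourly$timestamp
  if (!inherits(ts, "POSIXct")) ts <- as.POSIXct(ts, tz = "UTC")
  out <- lapply(split(seq_len(nrow(hourly)), hourly$station_id), function(idx) {
    tt <- ts[idx]
    dh <- diff(as.numeric(tt))
    if (length(dh) && any(abs(dh - 3600) > 1))
      stop_otv("hourly series is not strictly hourly-spaced",
               class = "format_error")
    v <- hourly$value[idx]
    ok <- hourly$valid[idx] & !is.na(v)
    v[!ok] <- NA_real_
    dates <- as.Date(tt, tz = "UTC")
    hours <- as.integer(format(tt, "%H", tz = "UTC")) + 1L  # ending hour 1..24
    udays <- unique(dates)
    # global hour index so windows can reach into the previous day
    mda8 <- vapply(udays, function(d) {
      day_pos <- which(dates == d)
      ends <- if (assign == "ending_hour") day_pos[hours[day_pos] >= 1] else
        day_pos[hours[day_pos] >= 8]
      wmeans <- rep(NA_real_, length(ends))
      for (k in seq_along(ends)) {
        lo <- ends[k] - 7L
        w <- v[seq(max(lo, 1L), ends[k])]
        if (lo < 1L) w <- c(rep(NA_real_, 1L - lo), w)
        nvalid <- sum(!is.na(w))
        if (nvalid >= min_valid_hours) wmeans[k] <- mean(w, na.rm = TRUE)
      }
      if (sum(!is.na(wmeans)) >= min_valid_windows)
        max(wmeans, na.rm = TRUE) else NA_real_
    }, numeric(1))
    data.frame(station_id = hourly$station_id[idx][1], date = udays,
               mda8o3 = mda8)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Joint seasonal data coverage of a daily series
#'
#' Fraction of season days in the base period on which *both* MDA8O3 and TX
#' are non-missing.
#'
#' @param daily data frame with `date`, `mda8o3`, `tx` columns (one station).
#' @param season_months months of the o-t-season (default April-September).
#' @param years base-period years.
#' @return fraction in \[0, 1\].
#' @export
season_coverage <- function(daily, season_months = 4:9, years) {
  days <- season_dates(years, season_months)
  if (!length(days))
    stop_otv("empty season/base period", class = "configuration_error")
  m <- match(days, as.Date(daily$date))
  both <- !is.na(m) & !is.na(daily$mda8o3[m]) & !is.na(daily$tx[m])
  sum(both) / length(days)
}

#' Great-circle distance in kilometres
#'
#' Haversine formula with Earth radius 6371.0 km.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorized).
#' @return distance in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180))
    stop_otv("coordinates out of range", class = "domain_error")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(a)))
}

#' Pair ozone stations with temperature stations
#'
#' Each ozone station is assigned its nearest temperature station among
#' those within `max_distance` km and `max_altitude_diff` m (ties broken by
#' smaller altitude difference, then lexicographic station id). Pairs whose
#' joint seasonal coverage does not exceed `min_coverage` are dropped. If
#' two ozone stations claim the same temperature station, only the pair
#' with the higher coverage is kept, so no temperature series is duplicated
#' across pairs. Pair location metadata is taken from the ozone site.
#'
#' @param ozone,temperature data frames of station metadata with columns
#'   `station_id`, `latitude`, `longitude`, `altitude` (and optionally
#'   `station_type`).
#' @param daily data frame of daily series with columns `station_id`,
#'   `date`, `mda8o3`, `tx`, where the ozone station's rows carry `mda8o3`
#'   and the temperature station's rows carry `tx`.
#' @param season_months,years coverage window, see [season_coverage()].
#' @param max_distance maximum pairing distance, km (default 15).
#' @param max_altitude_diff maximum altitude difference, m (default 200).
#' @param min_coverage minimum joint coverage, strict (default 0.75).
#' @return data frame of pairs: ozone/temperature ids, ozone-site
#'   coordinates and type, `distance_km`, `altitude_diff_m`, `coverage`.
#' @export
pair_stations <- function(ozone, temperature, daily, season_months = 4:9,
                          years, max_distance = 15, max_altitude_diff = 200,
                          min_coverage = 0.75) {
  stopifnot(all(c("station_id", "latitude", "longitude", "altitude") %in%
                  names(ozone)))
  cand <- lapply(seq_len(nrow(ozone)), function(i) {
    d <- haversine_km(ozone$latitude[i], ozone$longitude[i],
                      temperature$latitude, temperature$longitude)
    dz <- abs(ozone$altitude[i] - temperature$altitude)
    ok <- d <= max_distance & dz <= max_altitude_diff
    if (!any(ok)) return(NULL)
    j <- which(ok)[order(d[ok], dz[ok], temperature$station_id[ok])][1]
    o3 <- daily[daily$station_id == ozone$station_id[i],
                c("date", "mda8o3")]
    tx <- daily[daily$station_id == temperature$station_id[j],
                c("date", "tx")]
    joint <- merge(o3, tx, by = "date", all = TRUE)
    cov <- season_coverage(joint, season_months, years)
    if (cov <= min_coverage) return(NULL)
    data.frame(ozone_station = ozone$station_id[i],
               temperature_station = temperature$station_id[j],
               latitude = ozone$latitude[i], longitude = ozone$longitude[i],
               altitude = ozone$altitude[i],
               station_type = if ("station_type" %in% names(ozone))
                 ozone$station_type[i] else NA_character_,
               distance_km = d[j], altitude_diff_m = dz[j], coverage = cov)
  })
  pairs <- do.call(rbind, cand)
  if (is.null(pairs)) return(empty_pairs())
  # dedupe temperature stations: keep the higher-coverage pair
  pairs <- pairs[order(pairs$temperature_station, -pairs$coverage,
                       pairs$ozone_station), ]
  pairs <- pairs[!duplicated(pairs$temperature_station), ]
  pairs <- pairs[order(pairs$ozone_station), ]
  rownames(pairs) <- NULL
  pairs
}

empty_pairs <- function() {
  data.frame(ozone_station = character(), temperature_station = character(),
             latitude = numeric(), longitude = numeric(), altitude = numeric(),
             station_type = character(), distance_km = numeric(),
             altitude_diff_m = numeric(), coverage = numeric())
}
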