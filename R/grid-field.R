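#' Daily gridded field container
#'
#' Holds a daily field (e.g. mean sea-level pressure or an 850-hPa
#' predictor) on a regular latitude/longitude grid as a 3-d array with
#' dimensions `time x lat x lon`. Axes must be strictly monotone; they are
#' stored ascending internally so downstream indexing is orientation-free.
#'
#' @param var variable name, one of `"MSLP"`, `"GH"`, `"SH"`, `"MT"`, `"SSRD"`
#'   (other names allowed for synthetic experiments).
#' @param dates `Date` vector, one per time step.
#' @param lat,lon numeric axes in degrees, strictly monotone.
#' @param values numeric array `length(dates) x length(lat) x length(lon)`.
#' @param units unit string recorded as metadata.
#' @return an object of class `grid_field`.
#' @export
grid_field <- function(var, dates, lat, lon, values, units = "") {
  if (!all(dim(values) == c(length(dates), length(lat), length(lon))))
    stop_otv("values array does not match time/lat/lon axes",
             class = "input_error")
  dl <- diff(lat); dn <- diff(lon)
  if (length(dl) && !(all(dl > 0) || all(dl < 0)))
    stop_otv("latitude axis not monotone", class = "input_error")
  if (length(dn) && !(all(dn > 0) || all(dn < 0)))
    stop_otv("longitude axis not monotone", class = "input_error")
  if (length(dl) && all(dl < 0)) {
    lat <- rev(lat); values <- values[, rev(seq_along(lat)), , drop = FALSE]
  }
  if (length(dn) && all(dn < 0)) {
    lon <- rev(lon); values <- values[, , rev(seq_along(lon)), drop = FALSE]
  }
  if (any(!is.finite(values)))
    stop_otv("gridded field contains non-finite values", class = "input_error")
  structure(list(var = var, dates = dates, lat = lat, lon = lon,
                 values = values, units = units),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field> %s [%s]: %d days, %d x %d grid (%.1f..%.1fN, %.1f..%.1fE)\n",
              x$var, x$units, length(x$dates), length(x$lat), length(x$lon),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  invisible(x)
}

#' Flatten a gridded field to a day-by-cell matrix
#'
#' Cells are ordered row-major over the (lat, lon) grid: all longitudes of
#' the first latitude, then the second, and so on. This ordering is the one
#' used for SOM weight vectors and is recorded by the SOM model.
#'
#' @param field a [grid_field()].
#' @return numeric matrix `n_days x (n_lat*n_lon)`.
#' @export
flatten_field <- function(field) {
  nd <- length(field$dates); nla <- length(field$lat); nlo <- length(field$lon)
  m <- matrix(aperm(field$values, c(1, 3, 2)), nrow = nd, ncol = nla * nlo)
  # aperm gives time x lon x lat; columns are then lon-fastest within lat,
  # i.e. row-major over (lat, lon)
  m
}

#' Write / read a gridded field as long-format CSV
#'
#' Plain-text interchange for gridded fields (`date, lat, lon, value` rows
#' plus variable and unit columns).
#'
#' @param field a [grid_field()].
#' @param path file path.
#' @return `read_grid_csv` returns a [grid_field()].
#' @export
write_grid_csv <- function(field, path) {
  g <- expand.grid(lon = field$lon, lat = field$lat, date = field$dates,
                   KEEP.OUT.ATTRS = FALSE)
  df <- data.frame(var = field$var, date = g$date, lat = g$lat, lon = g$lon,
                   value = as.vector(aperm(field$values, c(3, 2, 1))),
                   units = field$units)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dates <- sort(unique(as.Date(df$date)))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  o <- order(match(as.Date(df$date), dates), match(df$lat, lat),
             match(df$lon, lon))
  arr <- array(NA_real_, c(length(dates), length(lat), length(lon)))
  arr[cbind(match(as.Date(df$date), dates), match(df$lat, lat),
            match(df$lon, lon))] <- df$value
  grid_field(df$var[1], dates, lat, lon, arr, units = df$units[1])
}
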