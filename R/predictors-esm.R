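#' Station-based predictor series from a gridded field
#'
#' Daily mean of the nine grid boxes (3 x 3 block) centred on the grid cell
#' containing the station. At domain edges the neighborhood is clipped and
#' the mean taken over the available cells.
#'
#' @param field a [grid_field()].
#' @param latitude,longitude station coordinates (the ozone site of the
#'   station pair).
#' @return data frame `date, value` plus attributes `variable`, `units`.
#' @export
extract_station_series <- function(field, latitude, longitude) {
  step_la <- if (length(field$lat) > 1) min(diff(field$lat)) else 1
  step_lo <- if (length(field$lon) > 1) min(diff(field$lon)) else 1
  i <- which.min(abs(field$lat - latitude))
  j <- which.min(abs(field$lon - longitude))
  if (abs(field$lat[i] - latitude) > step_la / 2 + 1e-9 ||
      abs(field$lon[j] - longitude) > step_lo / 2 + 1e-9)
    stop_otv("station outside gridded domain", class = "domain_error")
  ii <- intersect((i - 1):(i + 1), seq_along(field$lat))
  jj <- intersect((j - 1):(j + 1), seq_along(field$lon))
  block <- field$values[, ii, jj, drop = FALSE]
  v <- apply(block, 1, mean)
  out <- data.frame(date = field$dates, value = v)
  attr(out, "variable") <- field$var
  attr(out, "units") <- field$units
  out
}

#' Standardize a predictor series over a reference period
#'
#' @param x numeric vector (or data frame with `value`).
#' @param ref logical/integer index of the reference period rows (default:
#'   all).
#' @param params optional list `mean`/`sd` of stored parameters to apply
#'   instead of estimating.
#' @return list `values` (standardized vector), `mean`, `sd`.
#' @export
standardize_series <- function(x, ref = NULL, params = NULL) {
  v <- if (is.data.frame(x)) x$value else x
  if (is.null(params)) {
    r <- if (is.null(ref)) seq_along(v) else ref
    mu <- mean(v[r]); s <- stats::sd(v[r])
    if (!is.finite(s) || s == 0)
      stop_otv("zero standard deviation over the reference period",
               class = "standardization_error")
  } else { mu <- params$mean; s <- params$sd }
  list(values = (v - mu) / s, mean = mu, sd = s)
}

#' Pairwise Spearman agreement of station predictor series within a region
#'
#' @param series named list of numeric vectors (one per station, same
#'   dates) for a single predictor variable.
#' @param min_rho agreement threshold below which a pair is flagged
#'   (default 0.5).
#' @return data frame `station_a, station_b, rho, flagged` with one row per
#'   unordered station pair.
#' @export
agreement_check <- function(series, min_rho = 0.5) {
  ids <- names(series)
  if (length(ids) < 2) stop_otv("need at least 2 stations",
                                class = "input_error")
  pairs <- utils::combn(ids, 2)
  rho <- apply(pairs, 2, function(p) {
    x <- series[[p[1]]]; y <- series[[p[2]]]
    ok <- !is.na(x) & !is.na(y)
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      stop_otv("constant predictor series", class = "input_error")
    stats::cor(x[ok], y[ok], method = "spearman")
  })
  data.frame(station_a = pairs[1, ], station_b = pairs[2, ], rho = rho,
             flagged = rho < min_rho)
}

#' Bilinear regridding of a daily field
#'
#' Standard four-point bilinear interpolation of every daily slice onto new
#' latitude/longitude axes, which must lie inside the source hull (no
#' extrapolation).
#'
#' @param field a [grid_field()].
#' @param lat_out,lon_out target axes (monotone).
#' @return a [grid_field()] on the target axes.
#' @export
regrid_bilinear <- function(field, lat_out, lon_out) {
  lat_out <- sort(lat_out); lon_out <- sort(lon_out)
  if (min(lat_out) < min(field$lat) - 1e-9 ||
      max(lat_out) > max(field$lat) + 1e-9 ||
      min(lon_out) < min(field$lon) - 1e-9 ||
      max(lon_out) > max(field$lon) + 1e-9)
    stop_otv("target grid requires extrapolation", class = "domain_error")
  ia <- pmin(pmax(findInterval(lat_out, field$lat), 1), length(field$lat) - 1)
  ja <- pmin(pmax(findInterval(lon_out, field$lon), 1), length(field$lon) - 1)
  wa <- (lat_out - field$lat[ia]) / (field$lat[ia + 1] - field$lat[ia])
  wb <- (lon_out - field$lon[ja]) / (field$lon[ja + 1] - field$lon[ja])
  nd <- length(field$dates)
  out <- array(0, c(nd, length(lat_out), length(lon_out)))
  for (a in seq_along(lat_out)) for (b in seq_along(lon_out)) {
    f00 <- field$values[, ia[a], ja[b]]
    f01 <- field$values[, ia[a], ja[b] + 1]
    f10 <- field$values[, ia[a] + 1, ja[b]]
    f11 <- field$values[, ia[a] + 1, ja[b] + 1]
    out[, a, b] <- f00 * (1 - wa[a]) * (1 - wb[b]) +
      f01 * (1 - wa[a]) * wb[b] + f10 * wa[a] * (1 - wb[b]) +
      f11 * wa[a] * wb[b]
  }
  grid_field(field$var, field$dates, lat_out, lon_out, out,
             units = field$units)
}

#' Monthly linear-scaling bias correction
#'
#' Additive correction aligning ESM monthly means with a reference series:
#' `offset[m] = mean_ref(m) - mean_esm_hist(m)` is estimated on the
#' historical overlap and added to every ESM value of month `m`, in the
#' historical and scenario segments alike.
#'
#' @param esm_dates,esm_values the full ESM series (historical + scenario).
#' @param ref_dates,ref_values the reference (reanalysis-like) series.
#' @param hist_years years of the historical overlap used to estimate the
#'   offsets (default: years present in both series).
#' @param multiplicative use ratio scaling instead of additive offsets
#'   (off by default; additive matches the mean-difference correction).
#' @return list `values` (corrected ESM series) and `offsets` (length-12
#'   numeric, NA for months absent from the target series).
#' @export
bias_correct_monthly <- function(esm_dates, esm_values, ref_dates, ref_values,
                                 hist_years = NULL, multiplicative = FALSE) {
  esm_dates <- as.Date(esm_dates); ref_dates <- as.Date(ref_dates)
  hist_years <- hist_years %||%
    intersect(date_year(esm_dates), date_year(ref_dates))
  me <- date_month(esm_dates); mr <- date_month(ref_dates)
  he <- date_year(esm_dates) %in% hist_years
  hr <- date_year(ref_dates) %in% hist_years
  offsets <- rep(NA_real_, 12)
  months_needed <- sort(unique(me))
  for (m in months_needed) {
    if (!any(he & me == m) || !any(hr & mr == m))
      stop_otv("month ", m, " absent from the historical overlap",
               class = "correction_error")
    if (multiplicative) {
      offsets[m] <- mean(ref_values[hr & mr == m]) /
        mean(esm_values[he & me == m])
    } else {
      offsets[m] <- mean(ref_values[hr & mr == m]) -
        mean(esm_values[he & me == m])
    }
  }
  corrected <- if (multiplicative) esm_values * offsets[me] else
    esm_values + offsets[me]
  list(values = corrected, offsets = offsets)
}

#' Bias-correct a gridded field cell by cell
#'
#' Applies [bias_correct_monthly()] independently to every grid cell
#' (used for MSLP ahead of weather-type assignment).
#'
#' @param esm_field,ref_field [grid_field()]s on the same axes.
#' @param hist_years historical overlap years.
#' @return corrected [grid_field()].
#' @export
bias_correct_field <- function(esm_field, ref_field, hist_years = NULL) {
  if (!identical(esm_field$lat, ref_field$lat) ||
      !identical(esm_field$lon, ref_field$lon))
    stop_otv("fields are on different grids; regrid first",
             class = "input_error")
  out <- esm_field$values
  for (a in seq_along(esm_field$lat)) for (b in seq_along(esm_field$lon)) {
    out[, a, b] <- bias_correct_monthly(esm_field$dates,
                                        esm_field$values[, a, b],
                                        ref_field$dates,
                                        ref_field$values[, a, b],
                                        hist_years)$values
  }
  grid_field(esm_field$var, esm_field$dates, esm_field$lat, esm_field$lon,
             out, units = esm_field$units)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Distributional-similarity check between reference and bias-corrected ESM
#' predictor values. Reported only; never gates the pipeline.
#'
#' @param x,y numeric samples.
#' @param alpha significance level for the flag (default 0.05).
#' @return list `D`, `p_value`, `significant`.
#' @export
ks_compare <- function(x, y, alpha = 0.05) {
  if (!length(x) || !length(y)) stop_otv("empty sample", class = "input_error")
  kt <- suppressWarnings(stats::ks.test(x, y))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value),
       significant = unname(kt$p.value) < alpha)
}

#' Merged standardization of historical + scenario series
#'
#' Historical and scenario segments are concatenated, the mean and sd are
#' computed on the merged series, and both segments are standardized with
#' those joint parameters, so scenario-driven mean changes survive the
#' transform.
#'
#' @param hist,scen numeric vectors.
#' @return list `hist`, `scen` (standardized segments), `mean`, `sd`.
#' @export
merge_standardize <- function(hist, scen) {
  merged <- c(hist, scen)
  s <- stats::sd(merged)
  if (!is.finite(s) || s == 0)
    stop_otv("zero standard deviation of merged series",
             class = "standardization_error")
  mu <- mean(merged)
  list(hist = (hist - mu) / s, scen = (scen - mu) / s, mean = mu, sd = s)
}
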