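#' Configuration for the synthetic o-t study system
#'
#' Defines a synthetic station network with region-structured ozone and
#' temperature series, coherent gridded predictor fields with planted
#' pressure patterns, and pseudo-ESM bundles with known biases and warming
#' trends. Every downstream stage of the pipeline can be scored against the
#' ground truth this generator records.
#'
#' @param n_regions number of planted o-t-regions (>= 2).
#' @param stations_per_region stations per region (>= 1).
#' @param years calendar years of the observational base period.
#' @param season_months o-t-season months (default April-September).
#' @param region_params per-region data frame with columns `tx_mean` (deg C),
#'   `tx_amp` (seasonal amplitude, deg C), `ar_coef` (shared synoptic AR(1)
#'   coefficient), `ar_sd` (innovation sd, deg C), `station_sd` (station
#'   noise sd, deg C), `o3_intercept` (ug/m3), `o3_slope` (ug/m3 per deg C),
#'   `o3_sd` (ozone noise sd, ug/m3). Defaults emulate a central-European
#'   gradient with a shared AR(1) coefficient of 0.7 and an ozone response
#'   of 3 ug/m3 per deg C.
#' @param grid_spec list `lat = c(min, max)`, `lon = c(min, max)`,
#'   `step` (degrees); default the 1-degree European domain
#'   25-70N, 25W-40E.
#' @param n_patterns number of planted sea-level-pressure patterns
#'   (default 9, a 3x3 weather-type layout).
#' @param pattern_sd per-cell MSLP noise sd around the day's pattern (hPa).
#' @param mt_noise_sd per-cell noise sd of the 850-hPa temperature field
#'   (deg C); small values couple the field tightly to station TX.
#' @param esm_bias named list of length-12 numeric vectors (per-month
#'   additive offsets) per variable; defaults plant smooth seasonal biases
#'   of order 1-2 deg C (MT), 2 hPa (MSLP) and proportionate offsets for
#'   GH, SH, SSRD.
#' @param warming named vector of linear MT trends per scenario
#'   (deg C per decade, applied from the scenario period onward). Defaults
#'   0.33 (SSP245-like) and 0.60 (SSP370-like).
#' @param missing_rate completely-at-random missingness injected per
#'   variable (default 0.05).
#' @param seed integer master seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_regions = 6, stations_per_region = 10,
                         years = 2004:2018, season_months = 4:9,
                         region_params = NULL,
                         grid_spec = list(lat = c(25, 70), lon = c(-25, 40),
                                          step = 1),
                         n_patterns = 9, pattern_sd = 2, mt_noise_sd = 0.5,
                         esm_bias = NULL,
                         warming = c(SSP245 = 0.33, SSP370 = 0.60),
                         missing_rate = 0.05, seed = 1L) {
  if (n_regions < 2)
    stop_otv("n_regions must be >= 2", class = "configuration_error")
  if (stations_per_region < 1)
    stop_otv("stations_per_region must be >= 1",
             class = "configuration_error")
  if (!length(season_months))
    stop_otv("season_months must be non-empty", class = "configuration_error")
  region_params <- region_params %||% default_region_params(n_regions)
  if (nrow(region_params) != n_regions)
    stop_otv("region_params must have one row per region",
             class = "configuration_error")
  if (any(region_params$ar_sd <= 0) || any(region_params$station_sd <= 0) ||
      any(region_params$o3_sd <= 0) || pattern_sd <= 0 || mt_noise_sd <= 0)
    stop_otv("all noise standard deviations must be > 0",
             class = "configuration_error")
  esm_bias <- esm_bias %||% default_esm_bias()
  structure(list(n_regions = n_regions,
                 stations_per_region = stations_per_region,
                 years = years, season_months = season_months,
                 region_params = region_params, grid_spec = grid_spec,
                 n_patterns = n_patterns, pattern_sd = pattern_sd,
                 mt_noise_sd = mt_noise_sd, esm_bias = esm_bias,
                 warming = warming, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

default_region_params <- function(n) {
  data.frame(region = seq_len(n),
             tx_mean = seq(14, 27, length.out = n),
             tx_amp = seq(5, 7, length.out = n),
             ar_coef = 0.7, ar_sd = 1.5, station_sd = 0.8,
             o3_intercept = 25, o3_slope = 3, o3_sd = 8)
}

default_esm_bias <- function() {
  m <- 1:12
  list(MT = 1.2 * sin(2 * pi * (m - 1) / 12),
       MSLP = 2.0 * cos(2 * pi * (m - 1) / 12),
       GH = 5.0 * sin(2 * pi * (m - 3) / 12),
       SH = 3e-4 * cos(2 * pi * (m - 5) / 12),
       SSRD = 10 * sin(2 * pi * (m - 2) / 12))
}

grid_axes <- function(grid_spec, step = NULL) {
  step <- step %||% grid_spec$step
  lat <- seq(grid_spec$lat[1], grid_spec$lat[2], by = step)
  lon <- seq(grid_spec$lon[1], grid_spec$lon[2], by = step)
  # always include the domain edge so coarse grids span the full hull
  if (max(lat) < grid_spec$lat[2]) lat <- c(lat, grid_spec$lat[2])
  if (max(lon) < grid_spec$lon[2]) lon <- c(lon, grid_spec$lon[2])
  list(lat = lat, lon = lon)
}

region_centres <- function(config) {
  ax <- grid_axes(config$grid_spec)
  la <- range(ax$lat); lo <- range(ax$lon)
  nc <- ceiling(sqrt(config$n_regions))
  nr <- ceiling(config$n_regions / nc)
  g <- expand.grid(
    lat = seq(la[1] + 0.2 * diff(la), la[2] - 0.2 * diff(la),
              length.out = nr),
    lon = seq(lo[1] + 0.15 * diff(lo), lo[2] - 0.15 * diff(lo),
              length.out = nc))
  g[seq_len(config$n_regions), ]
}

#' Generate a synthetic station network
#'
#' Stations are scattered around their region's centre inside the gridded
#' domain, with non-negative altitudes and background station types.
#'
#' @param config a [synth_config()].
#' @return data frame `station_id, region, latitude, longitude, altitude,
#'   station_type`; the `region` column is the ground-truth label.
#' @export
synth_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  ctr <- region_centres(config)
  n <- config$n_regions * config$stations_per_region
  region <- rep(seq_len(config$n_regions), each = config$stations_per_region)
  ax <- grid_axes(config$grid_spec)
  lat <- pmin(pmax(ctr$lat[region] + stats::runif(n, -1.5, 1.5), min(ax$lat)),
              max(ax$lat))
  lon <- pmin(pmax(ctr$lon[region] + stats::runif(n, -1.5, 1.5), min(ax$lon)),
              max(ax$lon))
  data.frame(station_id = sprintf("ST%03d", seq_len(n)),
             region = region, latitude = lat, longitude = lon,
             altitude = round(abs(stats::rnorm(n, 150, 120))),
             station_type = sample(c("urban", "suburban", "rural"), n,
                                   replace = TRUE))
}

region_signal <- function(config, dates, seed_offset = 1L) {
  set.seed(config$seed + seed_offset)
  doy <- as.integer(strftime(dates, "%j"))
  nd <- length(dates)
  sig <- matrix(0, nd, config$n_regions)
  for (r in seq_len(config$n_regions)) {
    p <- config$region_params[r, ]
    seasonal <- p$tx_mean + p$tx_amp * cos(2 * pi * (doy - 199) / 365.25)
    syn <- numeric(nd)
    innov <- stats::rnorm(nd, 0, p$ar_sd)
    syn[1] <- innov[1] / sqrt(1 - p$ar_coef^2)
    for (d in 2:nd) syn[d] <- p$ar_coef * syn[d - 1] + innov[d]
    sig[, r] <- seasonal + syn
  }
  sig
}

#' Generate daily station series (TX and MDA8O3)
#'
#' TX is the region's seasonal cycle plus a synoptic AR(1) term shared by
#' all stations of the region plus independent station noise; MDA8O3
#' responds linearly to TX with a region-specific slope plus noise.
#' Missingness is injected completely at random per variable.
#'
#' @param config a [synth_config()].
#' @param network output of [synth_network()].
#' @return data frame `station_id, date, mda8o3, tx` over every calendar
#'   day of `config$years`, with attributes `region_signal` (days x regions
#'   TX signal without station noise) and `dates`.
#' @export
synth_daily_series <- function(config, network) {
  dates <- all_dates(config$years)
  sig <- region_signal(config, dates, seed_offset = 1L)
  set.seed(config$seed + 2L)
  nd <- length(dates)
  out <- lapply(seq_len(nrow(network)), function(i) {
    r <- network$region[i]
    p <- config$region_params[r, ]
    tx <- sig[, r] + stats::rnorm(nd, 0, p$station_sd)
    o3 <- p$o3_intercept + p$o3_slope * tx + stats::rnorm(nd, 0, p$o3_sd)
    if (config$missing_rate > 0) {
      tx[stats::runif(nd) < config$missing_rate] <- NA_real_
      o3[stats::runif(nd) < config$missing_rate] <- NA_real_
    }
    data.frame(station_id = network$station_id[i], date = dates,
               mda8o3 = o3, tx = tx)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "region_signal") <- sig
  attr(res, "dates") <- dates
  res
}

mslp_pattern_coefs <- function(config) {
  set.seed(config$seed + 3L)
  matrix(stats::rnorm(config$n_patterns * 6, 0, 4), config$n_patterns, 6)
}

mslp_basis_matrix <- function(config, lat, lon) {
  ax <- grid_axes(config$grid_spec)
  x <- (rep(lat, each = length(lon)) - min(ax$lat)) / diff(range(ax$lat))
  y <- (rep(lon, times = length(lat)) - min(ax$lon)) / diff(range(ax$lon))
  H <- cbind(sin(pi * x), cos(pi * x), sin(pi * y), cos(pi * y),
             sin(pi * x) * sin(pi * y), cos(pi * x) * cos(pi * y))
  1013 + mslp_pattern_coefs(config) %*% t(H)  # patterns x cells (row-major)
}

cell_region <- function(config, lat, lon) {
  ctr <- region_centres(config)
  cl <- rep(lat, each = length(lon))
  cn <- rep(lon, times = length(lat))
  vapply(seq_along(cl), function(i)
    which.min((ctr$lat - cl[i])^2 + (ctr$lon - cn[i])^2), integer(1))
}

gen_fields <- function(config, sig, dates, lat, lon, seed_offset,
                       pattern_labels = NULL) {
  if (length(lat) < 3 || length(lon) < 3)
    stop_otv("grid too small for 9-cell neighborhoods",
             class = "configuration_error")
  nd <- length(dates); ncell <- length(lat) * length(lon)
  basis <- mslp_basis_matrix(config, lat, lon)  # seeded by config$seed + 3
  set.seed(config$seed + seed_offset)
  labels <- pattern_labels %||%
    sample.int(config$n_patterns, nd, replace = TRUE)
  reg <- cell_region(config, lat, lon)
  regsig <- sig[, reg, drop = FALSE]                      # days x cells
  z <- scale(sig)[, reg, drop = FALSE]                    # standardized
  mk <- function(var, m, units) {
    arr <- array(0, c(nd, length(lat), length(lon)))
    arr[] <- aperm(array(t(m), c(length(lon), length(lat), nd)), c(3, 2, 1))
    grid_field(var, dates, lat, lon, arr, units = units)
  }
  noise <- function(sd_) matrix(stats::rnorm(nd * ncell, 0, sd_), nd, ncell)
  mslp <- basis[labels, , drop = FALSE] + noise(config$pattern_sd)
  mt <- regsig - 10 + noise(config$mt_noise_sd)
  gh <- 1500 + 12 * z + noise(3)
  sh <- 0.007 - 0.001 * z + noise(2e-4)
  ssrd <- 220 + 30 * z + noise(10)
  list(fields = list(MSLP = mk("MSLP", mslp, "hPa"),
                     MT = mk("MT", mt, "degC"),
                     GH = mk("GH", gh, "m"),
                     SH = mk("SH", sh, "kg/kg"),
                     SSRD = mk("SSRD", ssrd, "W/m2")),
       pattern_labels = labels, basis = basis)
}

#' Generate daily gridded predictor fields coherent with the stations
#'
#' MSLP days are noisy copies of one of `n_patterns` smooth planted basis
#' fields (the ground-truth weather types); the 850-hPa temperature field
#' follows the TX signal of the nearest region so 9-cell station
#' extractions correlate with station TX; GH, SH, SSRD are tied to the
#' standardized regional synoptic signal (SH negatively).
#'
#' @param config a [synth_config()].
#' @param network station table (used only to validate grid coverage).
#' @param series output of [synth_daily_series()] (provides the regional
#'   signal and dates).
#' @return list `fields` (named list of [grid_field()]s: MSLP, MT, GH, SH,
#'   SSRD), `pattern_labels` (ground-truth pattern id per day), and `basis`
#'   (patterns x cells matrix of the planted MSLP fields).
#' @export
synth_grids <- function(config, network, series) {
  ax <- grid_axes(config$grid_spec)
  if (any(network$latitude < min(ax$lat) | network$latitude > max(ax$lat) |
          network$longitude < min(ax$lon) | network$longitude > max(ax$lon)))
    stop_otv("grid does not cover all stations", class = "configuration_error")
  gen_fields(config, attr(series, "region_signal"), attr(series, "dates"),
             ax$lat, ax$lon, seed_offset = 4L)
}

#' Generate pseudo-ESM bundles (historical + scenarios)
#'
#' Each pseudo-model re-draws the synthetic atmosphere over the full
#' 1995-2100 period with its own seed on a coarser native grid, then adds
#' the configured per-month additive biases and, from the scenario period
#' onward, a linear warming trend on the 850-hPa temperature. Recorded
#' biases and trends are the ground truth for bias-correction and
#' projection tests.
#'
#' @param config a [synth_config()].
#' @param n_models number of pseudo-ESMs.
#' @param hist_years historical period (default 1995-2014).
#' @param scen_years scenario period (default 2015-2100).
#' @param coarse_step native ESM grid step in degrees (default 2; fields
#'   are later regridded back to the reference resolution by bilinear
#'   interpolation).
#' @param scenarios scenario names; defaults to `names(config$warming)`.
#' @return list of bundles, each a list `model_name`, `scenario`
#'   (`"historical"` or a scenario name), `fields` (named list of
#'   [grid_field()]s), `bias` (the planted offsets), `trend_per_decade`,
#'   `pattern_labels`.
#' @export
synth_esm <- function(config, n_models = 3, hist_years = 1995:2014,
                      scen_years = 2015:2100, coarse_step = 2,
                      scenarios = NULL) {
  scenarios <- scenarios %||% names(config$warming)
  if (!all(scenarios %in% names(config$warming)))
    stop_otv("scenario not configured in `warming`",
             class = "configuration_error")
  ax <- grid_axes(config$grid_spec, step = coarse_step)
  all_years <- c(hist_years, scen_years)
  dates <- all_dates(all_years)
  scen_start <- as.Date(paste0(min(scen_years), "-01-01"))
  months <- date_month(dates)
  bundles <- list()
  for (m in seq_len(n_models)) {
    sig <- region_signal(config, dates, seed_offset = 100L * m)
    g <- gen_fields(config, sig, dates, ax$lat, ax$lon,
                    seed_offset = 100L * m + 1L)
    biased <- lapply(names(g$fields), function(v) {
      f <- g$fields[[v]]
      f$values <- f$values + config$esm_bias[[v]][months]
      f
    })
    names(biased) <- names(g$fields)
    in_hist <- date_year(dates) %in% hist_years
    slice_fields <- function(fl, keep) lapply(fl, function(f)
      grid_field(f$var, f$dates[keep], f$lat, f$lon,
                 f$values[keep, , , drop = FALSE], units = f$units))
    bundles[[length(bundles) + 1]] <- list(
      model_name = sprintf("pESM%02d", m), scenario = "historical",
      fields = slice_fields(biased, in_hist), bias = config$esm_bias,
      trend_per_decade = 0, pattern_labels = g$pattern_labels[in_hist])
    for (sc in scenarios) {
      trend <- config$warming[[sc]]
      fl <- biased
      warm <- pmax(0, as.numeric(dates - scen_start) + 1) / 3652.5 * trend
      fl$MT$values <- fl$MT$values + warm
      keep <- !in_hist
      bundles[[length(bundles) + 1]] <- list(
        model_name = sprintf("pESM%02d", m), scenario = sc,
        fields = slice_fields(fl, keep), bias = config$esm_bias,
        trend_per_decade = trend, pattern_labels = g$pattern_labels[keep])
    }
  }
  bundles
}

#' Synthetic logistic training data with known coefficients
#'
#' Standardized iid normal predictors and a Bernoulli outcome from the
#' stated standardized logit coefficients; the ground truth for the
#' coefficient-recovery and driver-ranking tests.
#'
#' @param n number of days.
#' @param coefs named standardized coefficients (default the
#'   central-European-like truth MT 2.0, SH -1.0, SSRD 0.8, GH -0.3).
#' @param intercept logit intercept (default -2.5, an event rate under
#'   20 percent).
#' @param seed RNG seed.
#' @return list `X` (n x p matrix), `y` (0/1), `coefs`, `intercept`.
#' @export
synth_logistic <- function(n = 2700,
                           coefs = c(MT = 2.0, SH = -1.0, SSRD = 0.8,
                                     GH = -0.3),
                           intercept = -2.5, seed = 1) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * length(coefs)), n, length(coefs),
              dimnames = list(NULL, names(coefs)))
  eta <- intercept + as.vector(X %*% coefs)
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(X = X, y = y, coefs = coefs, intercept = intercept)
}

#' Assemble a full synthetic data set with ground truth
#'
#' Convenience wrapper running [synth_network()], [synth_daily_series()],
#' and [synth_grids()] and collecting the ground-truth labels.
#'
#' @param config a [synth_config()].
#' @return list `network`, `series`, `grids` (field list), `truth` (list:
#'   `region` per station, `pattern` per day, `esm_bias`, `warming`).
#' @export
synth_dataset <- function(config) {
  network <- synth_network(config)
  series <- synth_daily_series(config, network)
  grids <- synth_grids(config, network, series)
  list(network = network, series = series, grids = grids$fields,
       truth = list(region = stats::setNames(network$region,
                                             network$station_id),
                    pattern = grids$pattern_labels,
                    esm_bias = config$esm_bias,
                    warming = config$warming))
}
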