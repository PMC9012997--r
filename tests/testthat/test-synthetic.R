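default_esm_bias_names <- function() c("MT", "MSLP", "GH", "SH", "SSRD")

# mirror of the generator's default table, for slope manipulation in tests
default_region_params_test <- function(n) {
  data.frame(region = seq_len(n), tx_mean = seq(14, 27, length.out = n),
             tx_amp = seq(5, 7, length.out = n), ar_coef = 0.7, ar_sd = 1.5,
             station_sd = 0.8, o3_intercept = 25, o3_slope = 3, o3_sd = 8)
}

small_cfg <- function(...) {
  synth_config(n_regions = 2, stations_per_region = 3, years = 2010:2012,
               grid_spec = list(lat = c(45, 52), lon = c(5, 15), step = 1),
               n_patterns = 4, missing_rate = 0, seed = 5, ...)
}

test_that("network generation is deterministic with forced counts and labels", {
  cfg <- small_cfg()
  net <- synth_network(cfg)
  expect_equal(nrow(net), 6)
  expect_equal(net$region, rep(1:2, each = 3))
  expect_true(all(net$altitude >= 0))
  expect_true(all(net$station_type %in% c("urban", "suburban", "rural")))
  ax_lat <- c(45, 52); ax_lon <- c(5, 15)
  expect_true(all(net$latitude >= ax_lat[1] & net$latitude <= ax_lat[2]))
  expect_true(all(net$longitude >= ax_lon[1] & net$longitude <= ax_lon[2]))
  expect_identical(net, synth_network(small_cfg()))
  expect_error(synth_config(n_regions = 2, stations_per_region = 0),
               class = "otevents_error")
  expect_error(synth_config(n_regions = 1), class = "otevents_error")
})

test_that("daily series carry the planted o-t relationship and shared synoptics", {
  # slope 0: ozone independent of TX
  rp0 <- default_region_params_test(2)
  rp0$o3_slope <- 0
  cfg0 <- small_cfg(region_params = rp0)
  net <- synth_network(cfg0)
  ser <- synth_daily_series(cfg0, net)
  s1 <- ser[ser$station_id == "ST001", ]
  expect_gte(nrow(s1), 1000)
  expect_lt(abs(cor(s1$mda8o3, s1$tx, method = "spearman")), 0.1)

  # slope 3, small noise: strong positive rank correlation
  rp3 <- default_region_params_test(2)
  rp3$o3_slope <- 3; rp3$o3_sd <- 2
  cfg3 <- small_cfg(region_params = rp3)
  ser3 <- synth_daily_series(cfg3, synth_network(cfg3))
  s3 <- ser3[ser3$station_id == "ST001", ]
  expect_gt(cor(s3$mda8o3, s3$tx, method = "spearman"), 0.8)

  # shared synoptic term: within-region TX correlation beats cross-region
  wide <- reshape(ser3[, c("station_id", "date", "tx")], idvar = "date",
                  timevar = "station_id", direction = "wide")
  cmat <- cor(wide[, -1])
  within <- c(cmat[1, 2], cmat[1, 3], cmat[4, 5], cmat[4, 6])
  cross <- c(cmat[1, 4], cmat[2, 5], cmat[3, 6])
  expect_gt(min(within), max(cross))

  # missingness is injected at the configured rate
  cfgm <- synth_config(n_regions = 2, stations_per_region = 3,
                       years = 2010:2012,
                       grid_spec = list(lat = c(45, 52), lon = c(5, 15),
                                        step = 1),
                       n_patterns = 4, missing_rate = 0.05, seed = 5)
  serm <- synth_daily_series(cfgm, synth_network(cfgm))
  expect_lt(abs(mean(is.na(serm$tx)) - 0.05), 0.01)
})

test_that("gridded fields embed recoverable patterns and TX-coherent MT", {
  cfg <- small_cfg(pattern_sd = 0.5, mt_noise_sd = 0.3)
  dat <- synth_dataset(cfg)
  g <- synth_grids(cfg, dat$network, dat$series)
  # nearest-basis classification recovers planted labels
  m <- flatten_field(g$fields$MSLP)
  d2 <- outer(rowSums(m^2), rowSums(g$basis^2), "+") - 2 * m %*% t(g$basis)
  recovered <- apply(d2, 1, which.min)
  expect_gte(mean(recovered == g$pattern_labels), 0.95)

  # 9-cell MT mean tracks station TX under tight coupling
  st <- dat$network[1, ]
  mt9 <- extract_station_series(g$fields$MT, st$latitude, st$longitude)
  s1 <- dat$series[dat$series$station_id == st$station_id, ]
  expect_gt(cor(mt9$value, s1$tx, method = "spearman"), 0.9)

  # degenerate grid refuses 9-cell neighborhoods
  cfg_small <- synth_config(n_regions = 2, stations_per_region = 2,
                            years = 2010,
                            grid_spec = list(lat = c(45, 46), lon = c(5, 6),
                                             step = 1),
                            n_patterns = 2, seed = 1)
  net2 <- synth_network(cfg_small)
  ser2 <- synth_daily_series(cfg_small, net2)
  expect_error(synth_grids(cfg_small, net2, ser2),
               class = "otevents_error")
})

test_that("pseudo-ESMs carry the planted biases and warming trends", {
  cfg <- small_cfg()
  bundles <- synth_esm(cfg, n_models = 1, hist_years = 1995:2014,
                       scen_years = 2015:2100, coarse_step = 2)
  hist_b <- bundles[[which(vapply(bundles, function(b)
    b$scenario == "historical", logical(1)))]]
  # planted monthly MT bias: the same seed with zero bias regenerates the
  # identical noise, so month-mean differences equal the bias exactly
  zero_bias <- lapply(default_esm_bias_names(), function(v) rep(0, 12))
  names(zero_bias) <- default_esm_bias_names()
  cfg_nb <- small_cfg(esm_bias = zero_bias)
  bnb <- synth_esm(cfg_nb, n_models = 1, hist_years = 1995:2014,
                   scen_years = 2015:2100, coarse_step = 2)
  hist_nb <- bnb[[which(vapply(bnb, function(b)
    b$scenario == "historical", logical(1)))]]
  months <- as.integer(format(hist_b$fields$MT$dates, "%m"))
  planted <- cfg$esm_bias$MT
  for (m in c(1, 6)) {
    got <- mean(hist_b$fields$MT$values[months == m, , ]) -
      mean(hist_nb$fields$MT$values[months == m, , ])
    expect_equal(got, planted[m], tolerance = 1e-10)
  }

  # closed-form warming: trend t degC/decade from 2015 gives a late-century
  # minus historical mean of t * 7.55
  sc <- bundles[[which(vapply(bundles, function(b)
    b$scenario == "SSP245", logical(1)))]]
  full_dates <- c(hist_b$fields$MT$dates, sc$fields$MT$dates)
  mtfull <- c(apply(hist_b$fields$MT$values, 1, mean),
              apply(sc$fields$MT$values, 1, mean))
  an <- mt_anomaly(full_dates, mtfull)
  yrs_late <- 2081:2100
  expected <- cfg$warming[["SSP245"]] *
    mean(as.numeric(season_dates(yrs_late, 1:12) -
                      as.Date("2015-01-01")) + 1) / 3652.5
  expect_lt(abs(an$anomaly - expected), 0.2)

  # zero trend: scenario slices match historical within sampling error
  cfg0 <- small_cfg(warming = c(FLAT = 0))
  b0 <- synth_esm(cfg0, n_models = 1)
  h0 <- b0[[1]]; s0 <- b0[[2]]
  a0 <- mt_anomaly(c(h0$fields$MT$dates, s0$fields$MT$dates),
                   c(apply(h0$fields$MT$values, 1, mean),
                     apply(s0$fields$MT$values, 1, mean)))
  expect_lt(abs(a0$anomaly), 0.5)

  expect_error(synth_esm(cfg, scenarios = "SSP585"),
               class = "otevents_error")

  # determinism of bundles
  b1 <- synth_esm(small_cfg(), n_models = 1)
  b2 <- synth_esm(small_cfg(), n_models = 1)
  expect_identical(b1[[1]]$fields$MSLP$values, b2[[1]]$fields$MSLP$values)
})
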