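make_field <- function(vals_fun, lat = seq(45, 50), lon = seq(5, 12),
                       n_days = 10, var = "MT", units = "degC",
                       start = "2000-01-01") {
  arr <- array(NA_real_, c(n_days, length(lat), length(lon)))
  for (d in seq_len(n_days)) for (a in seq_along(lat))
    for (b in seq_along(lon)) arr[d, a, b] <- vals_fun(d, lat[a], lon[b])
  grid_field(var, as.Date(start) + seq_len(n_days) - 1, lat, lon, arr, units)
}

test_that("9-cell extraction averages the centred block and clips at edges", {
  f <- make_field(function(d, la, lo) 7)
  expect_true(all(extract_station_series(f, 47, 8)$value == 7))

  # centre cell 10, eight neighbours 1 -> (10 + 8)/9 = 2
  f2 <- make_field(function(d, la, lo) if (la == 47 && lo == 8) 10 else 1)
  expect_equal(extract_station_series(f2, 47, 8)$value[1], 2)

  # corner: 4 available cells
  f3 <- make_field(function(d, la, lo) {
    m <- rbind(c(2, 4), c(6, 8))
    if (la <= 46 && lo <= 6) m[la - 44, lo - 4] else 100
  })
  expect_equal(extract_station_series(f3, 45, 5)$value[1], 5)

  # orientation invariance: descending input axes give the same series
  set.seed(8)
  arr <- array(rnorm(10 * 6 * 8), c(10, 6, 8))
  fa <- grid_field("MT", as.Date("2000-01-01") + 0:9, seq(45, 50), seq(5, 12),
                   arr)
  fd <- grid_field("MT", as.Date("2000-01-01") + 0:9, rev(seq(45, 50)),
                   rev(seq(5, 12)),
                   arr[, rev(seq_len(6)), rev(seq_len(8)), drop = FALSE])
  expect_equal(extract_station_series(fa, 47, 8)$value,
               extract_station_series(fd, 47, 8)$value)

  expect_error(extract_station_series(fa, 60, 8), class = "otevents_error")
})

test_that("standardization round-trips and stores parameters", {
  set.seed(1)
  x <- rnorm(200, 10, 3)
  st <- standardize_series(x)
  expect_equal(mean(st$values), 0, tolerance = 1e-12)
  expect_equal(sd(st$values), 1, tolerance = 1e-12)
  expect_equal(st$values * st$sd + st$mean, x, tolerance = 1e-12)
  # applying stored parameters is affine and order-preserving
  y <- sort(rnorm(50, 12, 3))
  st2 <- standardize_series(y, params = list(mean = st$mean, sd = st$sd))
  expect_true(all(diff(st2$values) >= 0))
  expect_error(standardize_series(rep(3, 10)), class = "otevents_error")
})

test_that("within-region agreement reports pairwise Spearman rhos and flags", {
  # exact rank-formula case: x = 1,2,3 vs y = 3,1,2 -> rho = -0.5
  r <- agreement_check(list(a = c(1, 2, 3), b = c(3, 1, 2)))
  expect_equal(r$rho, -0.5)
  expect_true(r$flagged)

  set.seed(4)
  base <- rnorm(300)
  series <- list(s1 = base + rnorm(300, 0, 0.1),
                 s2 = base + rnorm(300, 0, 0.1),
                 s3 = rnorm(300))  # independent station
  rep_ <- agreement_check(series)
  expect_equal(nrow(rep_), choose(3, 2))
  expect_false(rep_$flagged[rep_$station_a == "s1" & rep_$station_b == "s2"])
  expect_true(all(rep_$flagged[rep_$station_a == "s3" |
                                 rep_$station_b == "s3"]))
  # reversal symmetry
  r2 <- agreement_check(list(a = base, b = -base))
  expect_equal(r2$rho, -1)
})

test_that("bilinear regridding is exact on linear fields and matches pracma", {
  f <- make_field(function(d, la, lo) 3.5)
  g <- regrid_bilinear(f, seq(45.5, 49.5), seq(5.5, 11.5))
  expect_true(all(g$values == 3.5))

  flin <- make_field(function(d, la, lo) 2 * la - 3 * lo + d)
  g2 <- regrid_bilinear(flin, c(45.3, 47.7), c(6.1, 10.9))
  for (a in 1:2) for (b in 1:2)
    expect_equal(g2$values[, a, b],
                 2 * g2$lat[a] - 3 * g2$lon[b] + seq_len(10),
                 tolerance = 1e-10)

  # midpoint of 4 cells 0,0 / 10,10 (by row) -> 5
  f4 <- grid_field("X", as.Date("2000-01-01"), c(0, 1), c(0, 1),
                   array(c(0, 10, 0, 10), c(1, 2, 2)))
  expect_equal(regrid_bilinear(f4, 0.5, 0.5)$values[1, 1, 1], 5)

  skip_if_not_installed("pracma")
  set.seed(12)
  fr <- make_field(function(d, la, lo) rnorm(1), n_days = 3)
  lat_t <- c(45.2, 47.9); lon_t <- c(5.4, 11.8)
  gr <- regrid_bilinear(fr, lat_t, lon_t)
  for (d in 1:3) {
    want <- pracma::interp2(fr$lon, fr$lat, fr$values[d, , ],
                            rep(lon_t, each = 2), rep(lat_t, 2),
                            method = "linear")
    expect_equal(as.vector(t(gr$values[d, , ])),
                 want[c(1, 3, 2, 4)], tolerance = 1e-10)
  }

  expect_error(regrid_bilinear(f, c(44, 46), c(6, 7)),
               class = "otevents_error")
})

test_that("monthly linear scaling removes planted mean biases exactly", {
  dates <- all_dates(2000:2004)
  set.seed(6)
  ref <- rnorm(length(dates), 15, 4)
  bias <- ifelse(format(dates, "%m") == "06", 2.0, 0)
  esm <- ref + bias
  bc <- bias_correct_monthly(dates, esm, dates, ref)
  expect_equal(bc$offsets[6], -2.0, tolerance = 1e-12)
  expect_equal(bc$offsets[1], 0, tolerance = 1e-12)
  # corrected monthly means equal reference monthly means to 1e-9
  for (m in 1:12) {
    idx <- format(dates, "%m") == sprintf("%02d", m)
    expect_equal(mean(bc$values[idx]), mean(ref[idx]), tolerance = 1e-9)
  }
  # zero-bias input is returned unchanged
  bc0 <- bias_correct_monthly(dates, ref, dates, ref)
  expect_equal(bc0$values, ref)
  expect_equal(unname(bc0$offsets[sort(unique(as.integer(format(dates, "%m"))))]),
               rep(0, 12))
  # KS distance never grows for a pure mean-shift bias
  shift <- ref + 1.5
  d_pre <- ks_compare(shift, ref)$D
  d_post <- ks_compare(bias_correct_monthly(dates, shift, dates, ref)$values,
                       ref)$D
  expect_lte(d_post, d_pre)
  # a target month absent from the reference overlap cannot be corrected
  expect_error(bias_correct_monthly(dates, esm, dates[1:30], ref[1:30]),
               class = "otevents_error")
})

test_that("KS comparison reproduces hand-enumerated statistics", {
  expect_equal(ks_compare(1:10, 1:10)$D, 0)
  expect_equal(ks_compare(1:5, 101:105)$D, 1)
  expect_equal(ks_compare(c(1, 2, 3, 4), c(3, 4, 5, 6))$D, 0.5)
  expect_error(ks_compare(numeric(0), 1:3), class = "otevents_error")
})

test_that("merged standardization preserves scenario mean shifts", {
  set.seed(13)
  hist <- rnorm(500, 10)
  scen <- rnorm(500, 12)  # warming scenario
  ms <- merge_standardize(hist, scen)
  merged <- c(ms$hist, ms$scen)
  expect_equal(mean(merged), 0, tolerance = 1e-12)
  expect_equal(sd(merged), 1, tolerance = 1e-12)
  expect_gt(mean(ms$scen), 0)
  expect_lt(mean(ms$hist), 0)
  # different scenarios give different parameters
  ms2 <- merge_standardize(hist, rnorm(500, 15))
  expect_false(isTRUE(all.equal(ms$mean, ms2$mean)))
  expect_error(merge_standardize(rep(1, 5), rep(1, 5)),
               class = "otevents_error")
})
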