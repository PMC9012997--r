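#' Station predictor/outcome training set
#'
#' Builds the standardized training set for one station: 9-cell means of
#' GH, MT, SH, SSRD around the site, the numeric weather-type code, and
#' the binary o-t-event outcome, restricted to season days of the base
#' period with complete events.
#'
#' @param grids named list of [grid_field()]s (MT, GH, SH, SSRD).
#' @param wt data frame `date, wt` from [assign_wt()].
#' @param events data frame from [detect_events()] for this station.
#' @param latitude,longitude station coordinates.
#' @param season_months,base_years season and base period.
#' @return list `X` (standardized matrix, columns GH, MT, SH, SSRD, WT),
#'   `y`, `dates`, `params` (per-column mean/sd used for standardization).
#' @export
build_training_set <- function(grids, wt, events, latitude, longitude,
                               season_months = 4:9, base_years) {
  days <- season_dates(base_years, season_months)
  vars <- c("GH", "MT", "SH", "SSRD")
  raw <- sapply(vars, function(v) {
    s <- extract_station_series(grids[[v]], latitude, longitude)
    s$value[match(days, s$date)]
  })
  wt_code <- wt$wt[match(days, as.Date(wt$date))]
  raw <- cbind(raw, WT = wt_code)
  params <- list()
  X <- raw
  for (j in colnames(raw)) {
    st <- standardize_series(raw[, j])
    X[, j] <- st$values
    params[[j]] <- list(mean = st$mean, sd = st$sd)
  }
  y <- events$ot_event[match(days, as.Date(events$date))]
  keep <- !is.na(y) & stats::complete.cases(X)
  list(X = X[keep, , drop = FALSE], y = y[keep], dates = days[keep],
       params = params)
}

#' Run the full compound-event modeling and projection pipeline
#'
#' End-to-end orchestration on a synthetic system: daily series and event
#' detection, Ward regionalization with elbow-selected cluster count,
#' representative-station selection, SOM weather typing of MSLP,
#' station-level SMOTE-balanced logistic downscaling with cross-validated
#' evaluation, pseudo-ESM bias correction, merged standardization,
#' weather-type assignment, and 20-year time-slice frequency-change
#' projections with ensemble summaries and MT stationarity diagnostics.
#'
#' @param config a [synth_config()].
#' @param som_shape SOM grid `c(rows, cols)` (default 3 x 3 = 9 weather
#'   types).
#' @param som_iterations SOM training iterations.
#' @param n_models number of pseudo-ESMs.
#' @param scenarios scenario names (default all configured).
#' @param folds,inner_folds outer/inner cross-validation folds.
#' @param f1_gate minimum cross-validated F1 a station model must reach to
#'   be projected (default 0.5).
#' @param k_min,k_max cluster-count search range (default 4 upward).
#' @param reps_per_region maximum representative stations per region
#'   (default 3: one per station type where present).
#' @param hist_years,scen_years,coarse_step pseudo-ESM setup, see
#'   [synth_esm()].
#' @param seed seed for model fitting/evaluation (default `config$seed`).
#' @return list with `network`, `events` (per-station summaries),
#'   `regions` (cluster solution), `k`, `representatives`, `som`,
#'   `wt_train`, `station_models` (per representative: report, model,
#'   threshold), `projections` (per station x model x scenario slice counts
#'   and changes), `ensembles` (ensemble summaries), `anomalies` (MT
#'   anomaly reports), `gated_out` (stations failing the F1 gate).
#' @export
run_ot_pipeline <- function(config, som_shape = c(3, 3),
                            som_iterations = 2000, n_models = 3,
                            scenarios = NULL, folds = 10, inner_folds = 10,
                            f1_gate = 0.5, k_min = 4, k_max = NULL,
                            reps_per_region = 3, hist_years = 1995:2014,
                            scen_years = 2015:2100, coarse_step = 2,
                            seed = NULL) {
  seed <- seed %||% config$seed
  scenarios <- scenarios %||% names(config$warming)
  dat <- synth_dataset(config)
  season <- config$season_months

  ## --- regionalization on imputed joint series ---
  imp <- impute_daily_means(dat$series)
  feats <- build_feature_matrix(imp$series, season, config$years)
  hc <- ward_cluster(feats, k = 2)  # linkage only; k decided next
  sel <- select_k(hc, k_min = k_min, k_max = k_max)
  solution <- ward_cluster(feats, k = sel$k)
  reps <- representative_stations(solution, feats, dat$network)
  reps <- do.call(rbind, lapply(split(reps, reps$region), function(d)
    utils::head(d[order(d$rank), ], reps_per_region)))

  ## --- events at representative stations ---
  ev <- list(); thr <- list()
  for (s in reps$station_id) {
    daily <- dat$series[dat$series$station_id == s, ]
    thr[[s]] <- tx_thresholds(daily, base_years = config$years,
                              season_months = season)
    ev[[s]] <- detect_events(daily, thr[[s]])
  }

  ## --- weather typing ---
  prep <- preprocess_mslp(dat$grids$MSLP)
  som <- train_som(prep$vectors, som_shape, iterations = som_iterations,
                   seed = seed, prep = prep)
  som$topographic_product <- topographic_product(som)
  wt_train <- assign_wt(dat$grids$MSLP, som)

  ## --- station downscaling models ---
  station_models <- list()
  for (i in seq_len(nrow(reps))) {
    s <- reps$station_id[i]
    st <- dat$network[dat$network$station_id == s, ]
    tr <- build_training_set(dat$grids, wt_train, ev[[s]],
                             st$latitude, st$longitude, season, config$years)
    # stations with too few events cannot support stratified CV (and
    # mirror the weak-linkage stations excluded from projection)
    if (min(sum(tr$y == 1), sum(tr$y == 0)) < max(folds, 6)) {
      station_models[[s]] <- list(station = st, region = reps$region[i],
                                  training = tr, report = NULL,
                                  model = NULL, p_star = NA_real_,
                                  drivers = NULL)
      next
    }
    rep_ <- evaluate_model(tr$X, tr$y, folds = folds,
                           inner_folds = inner_folds, seed = seed)
    station_models[[s]] <- list(station = st, region = reps$region[i],
                                training = tr, report = rep_,
                                model = rep_$final_model,
                                p_star = rep_$final_threshold,
                                drivers = rank_drivers(rep_$final_model))
  }
  passed <- names(station_models)[vapply(station_models,
                                         function(m) !is.null(m$report) &&
                                           m$report$f1 >= f1_gate,
                                         logical(1))]
  gated_out <- setdiff(names(station_models), passed)

  ## --- pseudo-ESM projections ---
  bundles <- synth_esm(config, n_models = n_models, hist_years = hist_years,
                       scen_years = scen_years, coarse_step = coarse_step,
                       scenarios = scenarios)
  ax <- grid_axes(config$grid_spec)
  overlap <- intersect(hist_years, config$years)
  slices <- list(historical = time_slice("historical", hist_years),
                 midcentury = time_slice("midcentury"),
                 late_century = time_slice("late_century"))
  proj_rows <- list(); anom_rows <- list()
  for (m in unique(vapply(bundles, `[[`, "", "model_name"))) {
    hist_b <- bundles[[which(vapply(bundles, function(b)
      b$model_name == m && b$scenario == "historical", logical(1)))]]
    for (sc in scenarios) {
      scen_b <- bundles[[which(vapply(bundles, function(b)
        b$model_name == m && b$scenario == sc, logical(1)))]]
      ## MSLP: regrid, cell-wise bias correction, WT assignment
      mslp_full <- cat_fields(hist_b$fields$MSLP, scen_b$fields$MSLP)
      mslp_fine <- regrid_bilinear(mslp_full, ax$lat, ax$lon)
      mslp_corr <- bias_correct_field(mslp_fine, dat$grids$MSLP,
                                      hist_years = overlap)
      wt_esm <- assign_wt(mslp_corr, som)
      esm_dates <- mslp_corr$dates
      in_hist <- date_year(esm_dates) %in% hist_years
      for (s in passed) {
        sm <- station_models[[s]]
        st <- sm$station
        pred <- data.frame(date = esm_dates)
        for (v in c("GH", "MT", "SH", "SSRD")) {
          full <- cat_fields(hist_b$fields[[v]], scen_b$fields[[v]])
          fine <- regrid_bilinear(full, ax$lat, ax$lon)
          ser <- extract_station_series(fine, st$latitude, st$longitude)
          ref <- extract_station_series(dat$grids[[v]], st$latitude,
                                        st$longitude)
          bc <- bias_correct_monthly(ser$date, ser$value, ref$date,
                                     ref$value, hist_years = overlap)
          ms <- merge_standardize(bc$values[in_hist], bc$values[!in_hist])
          pred[[v]] <- c(ms$hist, ms$scen)
          if (v == "MT") mt_raw <- bc$values
        }
        ms_wt <- merge_standardize(wt_esm$wt[in_hist], wt_esm$wt[!in_hist])
        pred$WT <- c(ms_wt$hist, ms_wt$scen)
        events_proj <- project_events(sm$model, sm$p_star, pred, season)
        counts <- vapply(slices, function(sl) count_slice(events_proj, sl),
                         numeric(1))
        proj_rows[[length(proj_rows) + 1]] <- data.frame(
          station_id = s, model_name = m, scenario = sc,
          n_hist = counts[["historical"]],
          n_mid = counts[["midcentury"]],
          n_late = counts[["late_century"]],
          change_mid = as.numeric(percent_change(counts[["historical"]],
                                                 counts[["midcentury"]])),
          change_late = as.numeric(percent_change(counts[["historical"]],
                                                  counts[["late_century"]])))
        for (sl in c("midcentury", "late_century")) {
          an <- mt_anomaly(esm_dates, mt_raw, slices$historical, slices[[sl]])
          anom_rows[[length(anom_rows) + 1]] <- data.frame(
            station_id = s, model_name = m, scenario = sc, slice = sl,
            anomaly = an$anomaly, warning = an$warning, severe = an$severe)
        }
      }
    }
  }
  projections <- do.call(rbind, proj_rows)
  anomalies <- do.call(rbind, anom_rows)
  ens_rows <- list()
  if (!is.null(projections)) {
    for (s in unique(projections$station_id))
      for (sc in unique(projections$scenario))
        for (sl in c("mid", "late")) {
          sub <- projections[projections$station_id == s &
                               projections$scenario == sc, ]
          es <- ensemble_summary(sub[[paste0("change_", sl)]])
          es$station_id <- s; es$scenario <- sc
          es$slice <- if (sl == "mid") "midcentury" else "late_century"
          ens_rows[[length(ens_rows) + 1]] <- es
        }
  }
  list(network = dat$network, truth = dat$truth,
       events = lapply(ev, event_summary),
       regions = solution, k = sel$k, k_gaps = sel$gaps,
       representatives = reps, som = som, wt_train = wt_train,
       station_models = station_models, projections = projections,
       ensembles = do.call(rbind, ens_rows), anomalies = anomalies,
       gated_out = gated_out)
}

# concatenate two fields of the same variable/grid along time
cat_fields <- function(a, b) {
  stopifnot(identical(a$lat, b$lat), identical(a$lon, b$lon))
  na <- length(a$dates); nb <- length(b$dates)
  arr <- array(NA_real_, c(na + nb, length(a$lat), length(a$lon)))
  arr[seq_len(na), , ] <- a$values
  arr[na + seq_len(nb), , ] <- b$values
  grid_field(a$var, c(a$dates, b$dates), a$lat, a$lon, arr, units = a$units)
}
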