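#' Standard 20-year time slices
#'
#' @param name one of `"historical"`, `"midcentury"`, `"late_century"`.
#' @return list `name`, `years` (integer vector). Defaults follow the
#'   CMIP6 convention: 1995-2014, 2041-2060, 2081-2100.
#' @export
time_slice <- function(name = c("historical", "midcentury", "late_century"),
                       years = NULL) {
  name <- match.arg(name)
  years <- years %||% switch(name, historical = 1995:2014,
                             midcentury = 2041:2060,
                             late_century = 2081:2100)
  list(name = name, years = years)
}

#' Project daily o-t-event indicators with ESM predictors
#'
#' Drives a fitted station downscaling model with preprocessed
#' (bias-corrected, merged-standardized, weather-typed) ESM predictors: a
#' day is an event when the modeled probability reaches the calibrated
#' threshold `p_star`. Season days only.
#'
#' @param model a `logistic_model`.
#' @param p_star calibrated probability threshold.
#' @param predictors data frame with a `date` column and one standardized
#'   column per retained predictor.
#' @param season_months months retained (default April-September).
#' @return data frame `date, prob, event`.
#' @export
project_events <- function(model, p_star, predictors, season_months = 4:9) {
  dts <- as.Date(predictors$date)
  keep <- date_month(dts) %in% season_months
  X <- as.matrix(predictors[keep, setdiff(names(predictors), "date"),
                            drop = FALSE])
  prob <- if (length(model$predictors)) predict_prob(model, X) else
    rep(stats::plogis(model$intercept), sum(keep))
  data.frame(date = dts[keep], prob = prob,
             event = as.integer(prob >= p_star))
}

#' Count event days inside a time slice
#'
#' @param events data frame with `date` and `event`.
#' @param slice a [time_slice()].
#' @return integer count.
#' @export
count_slice <- function(events, slice) {
  yrs <- date_year(as.Date(events$date))
  if (!any(yrs %in% slice$years))
    stop_otv("slice ", slice$name, " outside projected period",
             class = "domain_error")
  sum(events$event[yrs %in% slice$years], na.rm = TRUE)
}

#' Percent change in event frequency between time slices
#'
#' @param n_hist,n_future event-day counts.
#' @return percent change; `NA` with an `undefined` attribute when the
#'   historical count is zero.
#' @export
percent_change <- function(n_hist, n_future) {
  if (n_hist == 0) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  (n_future - n_hist) / n_hist * 100
}

#' Ensemble summary of projected changes across ESMs
#'
#' @param changes numeric vector of per-ESM percent changes for one
#'   station/scenario/slice.
#' @return one-row data frame: mean, median, min, max, number of ESMs, and
#'   the count sharing the majority sign.
#' @export
ensemble_summary <- function(changes) {
  changes <- changes[!is.na(changes)]
  if (!length(changes))
    return(data.frame(mean = NA_real_, median = NA_real_, min = NA_real_,
                      max = NA_real_, n_esm = 0L, sign_agreement = 0L))
  s <- sign(changes)
  maj <- if (sum(s >= 0) >= sum(s < 0)) 1 else -1
  data.frame(mean = mean(changes), median = stats::median(changes),
             min = min(changes), max = max(changes),
             n_esm = length(changes),
             sign_agreement = sum(s == maj | s == 0))
}

#' 850-hPa temperature anomaly and stationarity check
#'
#' Mean raw (un-standardized) MT difference between a future slice and the
#' historical slice, flagged against warning and severe levels. Large
#' anomalies indicate that statistical relationships fit in the base
#' period may not transfer to the projected climate.
#'
#' @param dates,mt the ESM MT series (raw deg C).
#' @param hist_slice,future_slice [time_slice()]s.
#' @param warn_level anomaly (deg C) above which the stationarity warning
#'   is raised (default 2.7).
#' @param severe_level severe-anomaly level (default 4.0).
#' @return list `anomaly`, `warning`, `severe`.
#' @export
mt_anomaly <- function(dates, mt, hist_slice = time_slice("historical"),
                       future_slice = time_slice("late_century"),
                       warn_level = 2.7, severe_level = 4.0) {
  yrs <- date_year(as.Date(dates))
  h <- mt[yrs %in% hist_slice$years]
  f <- mt[yrs %in% future_slice$years]
  if (!length(h) || !length(f))
    stop_otv("empty time slice", class = "input_error")
  a <- mean(f) - mean(h)
  list(anomaly = a, warning = a > warn_level, severe = a > severe_level)
}
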