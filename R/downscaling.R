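#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a binary training set exactly by interpolating new minority
#' samples: each synthetic point is `x + u * (x_nn - x)` for a random
#' minority sample `x`, one of its `k_neighbors` nearest minority
#' neighbors `x_nn`, and `u ~ U(0, 1)`. Original rows are preserved and
#' come first in the output.
#'
#' @param X numeric predictor matrix.
#' @param y binary outcome (0/1).
#' @param k_neighbors number of minority nearest neighbors (default 5).
#' @param seed RNG seed.
#' @return list `X`, `y` with equal class counts, and `synthetic` (logical
#'   marker per row, FALSE for originals).
#' @export
smote <- function(X, y, k_neighbors = 5, seed = 1) {
  X <- as.matrix(X)
  classes <- table(y)
  if (length(classes) != 2) stop_otv("y must have two classes",
                                     class = "resampling_error")
  minority <- as.numeric(names(classes)[which.min(classes)])
  n_min <- min(classes); n_maj <- max(classes)
  if (n_min < k_neighbors + 1)
    stop_otv("minority class too small for k = ", k_neighbors,
             " neighbors", class = "resampling_error")
  n_syn <- n_maj - n_min
  if (n_syn == 0)
    return(list(X = X, y = y, synthetic = rep(FALSE, length(y))))
  set.seed(seed)
  idx_min <- which(y == minority)
  Xm <- X[idx_min, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- do.call(rbind, lapply(seq_len(n_min), function(i)
    order(d[i, ])[seq_len(k_neighbors)]))
  base <- sample.int(n_min, n_syn, replace = TRUE)
  pick <- nn[cbind(base, sample.int(k_neighbors, n_syn, replace = TRUE))]
  u <- stats::runif(n_syn)
  Xs <- Xm[base, , drop = FALSE] + u * (Xm[pick, , drop = FALSE] -
                                          Xm[base, , drop = FALSE])
  list(X = rbind(X, Xs), y = c(y, rep(minority, n_syn)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, n_syn)))
}

#' Maximum-likelihood logistic regression with Wald statistics
#'
#' Unpenalized logit fit; standard errors come from the observed
#' information matrix, giving Wald z statistics and p-values per
#' coefficient. Non-convergence and (quasi-)separation are flagged rather
#' than regularized so coefficients stay interpretable.
#'
#' @param X numeric predictor matrix with column names.
#' @param y binary outcome (0/1).
#' @return object of class `logistic_model`: `intercept`, `coefficients`
#'   (named), `se`, `z`, `p_values`, `predictors`, `log_likelihood`,
#'   `null_log_likelihood`, `converged`, `separation`, `n`.
#' @export
fit_event_model <- function(X, y) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop_otv("outcome has a single class",
                                      class = "fit_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  df <- data.frame(.y = y, X, check.names = FALSE)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separation)
    warning("possible separation: coefficients from capped iterations",
            call. = FALSE)
  sm <- summary(fit)$coefficients
  co <- stats::coef(fit)
  nms <- names(co)[-1]
  p0 <- mean(y)
  null_ll <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  structure(list(intercept = unname(co[1]),
                 coefficients = stats::setNames(unname(co[-1]), nms),
                 se = stats::setNames(sm[-1, 2], nms),
                 z = stats::setNames(sm[-1, 3], nms),
                 p_values = stats::setNames(sm[-1, 4], nms),
                 predictors = nms,
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 null_log_likelihood = null_ll,
                 converged = fit$converged, separation = separation,
                 n = length(y)),
            class = "logistic_model")
}

#' Predict event probabilities from a fitted logistic model
#'
#' @param model a `logistic_model`.
#' @param X predictor matrix containing (at least) the model's retained
#'   predictor columns.
#' @return numeric vector of probabilities.
#' @export
predict_prob <- function(model, X) {
  X <- as.matrix(X)
  missing <- setdiff(model$predictors, colnames(X))
  if (length(missing))
    stop_otv("predictors missing from input: ",
             paste(missing, collapse = ", "), class = "input_error")
  eta <- model$intercept +
    as.vector(X[, model$predictors, drop = FALSE] %*% model$coefficients)
  stats::plogis(eta)
}

#' Backward elimination by Wald significance
#'
#' Iteratively refits the station model, dropping the single predictor with
#' the largest Wald p-value above `alpha`, until every retained predictor
#' is significant. If all predictors are eliminated, an intercept-only
#' model is returned with `degenerate = TRUE`.
#'
#' @param X predictor matrix with column names.
#' @param y binary outcome.
#' @param alpha significance level (default 0.05).
#' @return a `logistic_model` with an `elimination_trace` attribute
#'   (character vector of dropped predictors in order) and `degenerate`
#'   flag.
#' @export
backward_eliminate <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  keep <- colnames(X)
  trace <- character(0)
  repeat {
    if (!length(keep)) {
      m <- structure(list(intercept = stats::qlogis(mean(y)),
                          coefficients = stats::setNames(numeric(0), NULL),
                          se = numeric(0), z = numeric(0),
                          p_values = numeric(0), predictors = character(0),
                          log_likelihood = sum(y * log(mean(y)) +
                                                 (1 - y) * log(1 - mean(y))),
                          null_log_likelihood = sum(y * log(mean(y)) +
                                                      (1 - y) * log(1 - mean(y))),
                          converged = TRUE, separation = FALSE,
                          n = length(y)),
                     class = "logistic_model")
      m$degenerate <- TRUE
      m$elimination_trace <- trace
      return(m)
    }
    m <- fit_event_model(X[, keep, drop = FALSE], y)
    if (all(m$p_values <= alpha)) {
      m$degenerate <- FALSE
      m$elimination_trace <- trace
      return(m)
    }
    worst <- names(which.max(m$p_values))
    trace <- c(trace, worst)
    keep <- setdiff(keep, worst)
  }
}

#' Rank o-t-event drivers by standardized coefficient magnitude
#'
#' Orders the retained predictors by the absolute value of their
#' standardized regression coefficients; the top three are the most,
#' second, and third most important drivers (MID, SMID, TMID). Ties are
#' broken by the fixed column order GH, MT, SH, SSRD, WT.
#'
#' @param model a `logistic_model` on standardized predictors.
#' @param tie_order predictor order used to break magnitude ties.
#' @return data frame `rank, role, predictor, coefficient` (at most three
#'   rows).
#' @export
rank_drivers <- function(model, tie_order = c("GH", "MT", "SH", "SSRD", "WT")) {
  co <- model$coefficients
  if (!length(co))
    return(data.frame(rank = integer(), role = character(),
                      predictor = character(), coefficient = numeric()))
  pref <- match(names(co), tie_order)
  pref[is.na(pref)] <- length(tie_order) + seq_len(sum(is.na(pref)))
  o <- order(-abs(co), pref)
  top <- utils::head(o, 3)
  data.frame(rank = seq_along(top),
             role = c("MID", "SMID", "TMID")[seq_along(top)],
             predictor = names(co)[top],
             coefficient = unname(co[top]))
}

#' McFadden pseudo-R-squared
#'
#' `1 - lnL_model / lnL_null`, with the null model an intercept-only fit on
#' the same data.
#'
#' @param model a `logistic_model`.
#' @param X,y optional data to evaluate on; defaults to the training-fit
#'   log-likelihoods stored on the model.
#' @return numeric scalar.
#' @export
mcfadden_r2 <- function(model, X = NULL, y = NULL) {
  if (is.null(X)) {
    ll <- model$log_likelihood; ll0 <- model$null_log_likelihood
  } else {
    p <- predict_prob(model, X)
    ll <- sum(y * log(p) + (1 - y) * log(1 - p))
    p0 <- mean(y)
    if (p0 == 0 || p0 == 1)
      stop_otv("degenerate single-class outcome", class = "input_error")
    ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  }
  if (ll0 == 0) stop_otv("null log-likelihood is zero", class = "input_error")
  1 - ll / ll0
}

#' Precision, recall, and F1 at a probability threshold
#'
#' Predicts an event when the modeled probability is at least `threshold`.
#' Zero-denominator metrics are reported as 0 with `undefined = TRUE`.
#'
#' @param y_true binary outcomes.
#' @param y_prob modeled probabilities.
#' @param threshold probability cutoff in (0, 1).
#' @return list `precision`, `recall`, `f1`, `undefined`.
#' @export
classification_metrics <- function(y_true, y_prob, threshold) {
  if (length(y_true) != length(y_prob))
    stop_otv("length mismatch", class = "input_error")
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1 & y_true == 1)
  fp <- sum(pred == 1 & y_true == 0)
  fn <- sum(pred == 0 & y_true == 1)
  undefined <- FALSE
  p <- if (tp + fp == 0) { undefined <- TRUE; 0 } else tp / (tp + fp)
  r <- if (tp + fn == 0) { undefined <- TRUE; 0 } else tp / (tp + fn)
  f1 <- if (p + r == 0) { undefined <- TRUE; 0 } else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1, undefined = undefined)
}

fit_pipeline <- function(X, y, alpha = 0.05, k_neighbors = 5, seed = 1) {
  bal <- smote(X, y, k_neighbors = k_neighbors, seed = seed)
  backward_eliminate(bal$X, bal$y, alpha = alpha)
}

#' Calibrate the event probability threshold by cross-validation
#'
#' Upstream ten-fold procedure: per fold, the full training pipeline
#' (SMOTE, backward elimination, logit fit) is refit on the training part
#' and precision/recall are computed on the held-out part for every
#' candidate threshold 0.01..0.99. The threshold minimizing the fold-mean
#' |P - R| is selected (ties: nearest 0.5, then smaller).
#'
#' @param X,y training data (original, unbalanced).
#' @param folds number of folds (default 10).
#' @param grid candidate thresholds.
#' @param alpha elimination level.
#' @param k_neighbors SMOTE neighbors.
#' @param seed RNG seed (folds and SMOTE).
#' @return list `threshold` (p*), `objective` (named vector of mean |P-R|).
#' @export
calibrate_threshold <- function(X, y, folds = 10,
                                grid = seq(0.01, 0.99, by = 0.01),
                                alpha = 0.05, k_neighbors = 5, seed = 1) {
  X <- as.matrix(X)
  set.seed(seed)
  f <- stratified_folds(y, folds)
  gap <- matrix(NA_real_, folds, length(grid))
  for (i in seq_len(folds)) {
    tr <- f != i
    m <- fit_pipeline(X[tr, , drop = FALSE], y[tr], alpha, k_neighbors,
                      seed = seed + i)
    prob <- if (length(m$predictors))
      predict_prob(m, X[!tr, , drop = FALSE]) else
        rep(stats::plogis(m$intercept), sum(!tr))
    gap[i, ] <- vapply(grid, function(th) {
      cm <- classification_metrics(y[!tr], prob, th)
      # thresholds that predict no event (or meet no event) carry no
      # precision/recall information and are excluded from the search
      if (cm$undefined) NA_real_ else abs(cm$precision - cm$recall)
    }, numeric(1))
  }
  obj <- colMeans(gap)                       # NA unless defined in all folds
  if (all(is.na(obj))) obj <- colMeans(gap, na.rm = TRUE)
  if (all(is.na(obj)))
    stop_otv("no threshold yields defined precision/recall",
             class = "calibration_error")
  best <- which(obj == min(obj, na.rm = TRUE))
  best <- best[order(abs(grid[best] - 0.5), grid[best])][1]
  list(threshold = grid[best],
       objective = stats::setNames(obj, format(grid)))
}

#' Cross-validated evaluation of a station downscaling model
#'
#' Outer stratified ten-fold cross-validation; inside every training fold
#' the pipeline is SMOTE rebalancing, Wald backward elimination, the logit
#' fit, and an inner threshold calibration. Precision, recall, and F1 are
#' computed on the untouched validation folds at the fold's calibrated
#' threshold; McFadden R2 is the training-fit value per fold. Validation
#' folds never contain synthetic samples.
#'
#' @param X,y training data (original, unbalanced).
#' @param folds outer folds (default 10).
#' @param inner_folds folds of the nested threshold calibration
#'   (default 10).
#' @param alpha,k_neighbors pipeline settings.
#' @param seed RNG seed; the full report is reproducible given it.
#' @return object of class `performance_report`: `precision`, `recall`,
#'   `f1`, `mcfadden`, `threshold` (fold means), `per_fold` data frame,
#'   `events_per_variable`, `final_model` (pipeline refit on all data),
#'   `final_threshold`.
#' @export
evaluate_model <- function(X, y, folds = 10, inner_folds = 10, alpha = 0.05,
                           k_neighbors = 5, seed = 1) {
  X <- as.matrix(X)
  set.seed(seed)
  f <- stratified_folds(y, folds)
  rows <- list()
  for (i in seq_len(folds)) {
    tr <- f != i
    cal <- calibrate_threshold(X[tr, , drop = FALSE], y[tr],
                               folds = inner_folds, alpha = alpha,
                               k_neighbors = k_neighbors,
                               seed = seed * 1000 + i)
    m <- fit_pipeline(X[tr, , drop = FALSE], y[tr], alpha, k_neighbors,
                      seed = seed * 1000 + i)
    prob <- if (length(m$predictors))
      predict_prob(m, X[!tr, , drop = FALSE]) else
        rep(stats::plogis(m$intercept), sum(!tr))
    cm <- classification_metrics(y[!tr], prob, cal$threshold)
    rows[[i]] <- data.frame(fold = i, n_val = sum(!tr),
                            precision = cm$precision,
                            recall = cm$recall, f1 = cm$f1,
                            mcfadden = mcfadden_r2(m),
                            threshold = cal$threshold)
  }
  per_fold <- do.call(rbind, rows)
  final_cal <- calibrate_threshold(X, y, folds = inner_folds, alpha = alpha,
                                   k_neighbors = k_neighbors, seed = seed)
  final <- fit_pipeline(X, y, alpha, k_neighbors, seed = seed)
  structure(list(precision = mean(per_fold$precision),
                 recall = mean(per_fold$recall),
                 f1 = mean(per_fold$f1),
                 mcfadden = mean(per_fold$mcfadden),
                 threshold = mean(per_fold$threshold),
                 per_fold = per_fold,
                 events_per_variable = sum(y == 1) / ncol(X),
                 final_model = final,
                 final_threshold = final_cal$threshold),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf(paste0("<performance_report> P=%.3f R=%.3f F1=%.3f ",
                     "MF-R2=%.3f p*=%.2f (events/var=%.1f)\n"),
              x$precision, x$recall, x$f1, x$mcfadden, x$final_threshold,
              x$events_per_variable))
  invisible(x)
}
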