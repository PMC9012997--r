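# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# MDA8 oracle: straight enumeration over a padded hourly vector.
# values/valid are length 24*ndays (hour 1..24 per day). A window ending at
# hour h of day d covers the 8 hours ending there; hours before the series
# start count as invalid. Mean over valid hours when >= min_hours valid;
# day value = max over valid windows when >= min_windows of them.
oracle_mda8 <- function(values, valid, min_windows = 18, min_hours = 6) {
  n_days <- length(values) / 24
  v <- ifelse(valid, values, NA_real_)
  pad <- rep(NA_real_, 7)
  vv <- c(pad, v)
  out <- numeric(n_days)
  for (d in seq_len(n_days)) {
    wins <- rep(NA_real_, 24)
    for (h in 1:24) {
      end <- (d - 1) * 24 + h + 7   # index into padded vector
      w <- vv[(end - 7):end]
      if (sum(!is.na(w)) >= min_hours) wins[h] <- mean(w, na.rm = TRUE)
    }
    out[d] <- if (sum(!is.na(wins)) >= min_windows)
      max(wins, na.rm = TRUE) else NA_real_
  }
  out
}

make_hourly <- function(values, valid = rep(TRUE, length(values)),
                        start = "2010-06-01", station = "S1") {
  n <- length(values)
  data.frame(station_id = station,
             timestamp = as.POSIXct(start, tz = "UTC") +
               3600 * (seq_len(n) - 1),
             value = values, valid = valid)
}

# Ward agglomeration oracle: O(n^3) greedy merging minimizing the increase
# in within-cluster sum of squares; returns merge heights on the
# sqrt(2 * dESS) scale and the labels at a requested k.
oracle_ward <- function(X, k_keep = 2) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  labels_at <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      a <- clusters[[i]]; b <- clusters[[j]]
      ca <- colMeans(X[a, , drop = FALSE]); cb <- colMeans(X[b, , drop = FALSE])
      d <- length(a) * length(b) / (length(a) + length(b)) *
        sum((ca - cb)^2)
      if (d < best[1]) best <- c(d, i, j)
    }
    heights <- c(heights, sqrt(2 * best[1]))
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
    if (length(clusters) == k_keep) {
      lab <- integer(nrow(X))
      for (c in seq_along(clusters)) lab[clusters[[c]]] <- c
      labels_at[[as.character(k_keep)]] <- lab
    }
  }
  list(heights = heights, labels = labels_at[[as.character(k_keep)]])
}

# Bauer-Pawelzik topographic product, naive nested-loop form.
oracle_tp <- function(weights, rows, cols) {
  n <- nrow(weights)
  pos <- cbind(rep(seq_len(rows), each = cols), rep(seq_len(cols), rows))
  dv <- function(a, b) sqrt(sum((weights[a, ] - weights[b, ])^2))
  da <- function(a, b) sqrt(sum((pos[a, ] - pos[b, ])^2))
  total <- 0
  for (j in 1:n) {
    others <- setdiff(1:n, j)
    nv <- others[order(sapply(others, dv, a = j), others)]
    na_ <- others[order(sapply(others, da, a = j), others)]
    for (k in 1:(n - 1)) {
      p3 <- 1
      for (l in 1:k)
        p3 <- p3 * (dv(j, na_[l]) / dv(j, nv[l])) *
          (da(j, na_[l]) / da(j, nv[l]))
      total <- total + log(p3^(1 / (2 * k)))
    }
  }
  total / (n * (n - 1))
}

# Gradient-free logistic maximum likelihood (Nelder-Mead on the deviance).
oracle_logit <- function(X, y) {
  nll <- function(b) {
    eta <- b[1] + X %*% b[-1]
    -sum(y * eta - log1p(exp(eta)))
  }
  stats::optim(rep(0, ncol(X) + 1), nll,
               control = list(maxit = 5000, reltol = 1e-12))$par
}

# small complete daily series for one station
make_daily <- function(dates, tx, mda8o3 = NULL, station = "S1") {
  data.frame(station_id = station, date = dates,
             mda8o3 = mda8o3 %||% rep(50, length(dates)), tx = tx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
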