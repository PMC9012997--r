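#' Impute missing daily values with daily means
#'
#' Network-wise imputation: a station's missing value on date `d` is
#' replaced by the mean over all stations reporting that variable on `d`
#' (default). The per-station calendar-day mean is available as an
#' alternative (`method = "calendar"`).
#'
#' @param daily long data frame `station_id, date, mda8o3, tx`.
#' @param method `"network"` (cross-station same-date mean, default) or
#'   `"calendar"` (per-station calendar-day mean across years).
#' @return list with `series` (completed data frame) and `log`
#'   (data frame of station/date/variable rows that were imputed).
#' @export
impute_daily_means <- function(daily, method = c("network", "calendar")) {
  method <- match.arg(method)
  out <- daily
  logs <- list()
  for (v in c("mda8o3", "tx")) {
    x <- out[[v]]
    miss <- is.na(x)
    if (!any(miss)) next
    if (method == "network") {
      mu <- tapply(x, as.character(out$date), mean, na.rm = TRUE)
      fill <- mu[as.character(out$date[miss])]
    } else {
      key <- paste(out$station_id, date_mmdd(as.Date(out$date)))
      mu <- tapply(x, key, mean, na.rm = TRUE)
      fill <- mu[key[miss]]
    }
    if (any(!is.finite(fill)))
      stop_otv("no station reports ", v, " on some date; cannot impute",
               class = "imputation_error")
    out[[v]][miss] <- as.numeric(fill)
    logs[[v]] <- data.frame(station_id = daily$station_id[miss],
                            date = as.Date(daily$date[miss]), variable = v)
  }
  list(series = out, log = if (length(logs)) do.call(rbind, logs) else
    data.frame(station_id = character(), date = as.Date(character()),
               variable = character()))
}

#' Joint standardized TX/MDA8O3 feature matrix for clustering
#'
#' One row per station: the station's seasonal TX series standardized to
#' mean 0 / sd 1, concatenated with its standardized MDA8O3 series, over
#' all season days of the base period. Input must be complete (impute
#' first).
#'
#' @param daily completed long data frame `station_id, date, mda8o3, tx`.
#' @param season_months,base_years season and base period.
#' @return matrix `n_stations x (2 * n_season_days)` with station ids as
#'   row names; attribute `n_days` records the block length.
#' @export
build_feature_matrix <- function(daily, season_months = 4:9, base_years) {
  days <- season_dates(base_years, season_months)
  ids <- sort(unique(daily$station_id))
  dts <- as.Date(daily$date)
  blocks <- lapply(ids, function(s) {
    rows <- daily[daily$station_id == s, ]
    m <- match(days, as.Date(rows$date))
    if (any(is.na(m)))
      stop_otv("station ", s, " does not cover all season days",
               class = "input_error")
    tx <- rows$tx[m]; o3 <- rows$mda8o3[m]
    if (anyNA(tx) || anyNA(o3))
      stop_otv("station ", s, " has missing values; impute first",
               class = "input_error")
    std <- function(x) {
      s2 <- stats::sd(x)
      if (s2 == 0) stop_otv("zero-variance series for station ", s,
                            class = "standardization_error")
      (x - mean(x)) / s2
    }
    c(std(tx), std(o3))
  })
  m <- do.call(rbind, blocks)
  rownames(m) <- ids
  attr(m, "n_days") <- length(days)
  m
}

#' Ward hierarchical clustering of stations
#'
#' Agglomerative clustering with Ward's variance-minimization criterion on
#' Euclidean distances (each merge minimizes the increase in total
#' within-cluster variance). Heights are on the Euclidean scale, i.e. the
#' height of a merge equals `sqrt(2 * dESS)` where `dESS` is the increase
#' in within-cluster sum of squares.
#'
#' @param features matrix from [build_feature_matrix()] (row names = ids).
#' @param k number of clusters to cut at (k >= 1, < n stations).
#' @return object of class `cluster_solution`: list with `merge`, `height`
#'   (hclust encoding), `labels` (named integer vector 1..k), `k`,
#'   `centroids` (k x p), `sizes`, `station_ids`.
#' @export
ward_cluster <- function(features, k) {
  ids <- rownames(features)
  if (anyDuplicated(ids)) stop_otv("duplicate station ids",
                                   class = "input_error")
  if (k > nrow(features) || k < 1)
    stop_otv("k must be in 1..n_stations", class = "configuration_error")
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  # relabel clusters 1..k in order of first appearance for stability
  labels <- match(labels, unique(labels[order(ids)]))
  names(labels) <- ids
  centroids <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(features[labels == c, , drop = FALSE])))
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = labels, k = k, centroids = centroids,
                 sizes = as.integer(table(labels)), station_ids = ids,
                 hclust = hc),
            class = "cluster_solution")
}

#' Select the number of o-t-regions by the elbow criterion
#'
#' Operationalizes dendrogram/elbow inspection as the largest gap between
#' successive Ward merge heights: cutting at `k` clusters removes the merge
#' of height `h[n-k+1]`, so the score of `k` is `h[n-k+1] - h[n-k]`. The
#' `k` in `k_min..k_max` with the largest gap is returned; if no merge gap
#' is positive (featureless data), `k_min` is returned.
#'
#' @param solution a `cluster_solution` (or `hclust` object).
#' @param k_min minimum admissible cluster count (default 4, so that broad
#'   geographical differences are always resolved).
#' @param k_max maximum cluster count considered.
#' @return list with `k`, and `gaps` (named vector of height gaps).
#' @export
select_k <- function(solution, k_min = 4, k_max = NULL) {
  h <- if (inherits(solution, "hclust")) solution$height else solution$height
  n <- length(h) + 1
  k_max <- k_max %||% max(k_min, min(n - 1, 12))
  if (k_max < k_min)
    stop_otv("k_max < k_min", class = "configuration_error")
  k_max <- min(k_max, n - 1)
  ks <- k_min:k_max
  gaps <- vapply(ks, function(k) {
    upper <- h[n - k + 1]
    lower <- if (n - k >= 1) h[n - k] else 0
    upper - lower
  }, numeric(1))
  names(gaps) <- ks
  k <- if (all(gaps <= 0)) k_min else ks[which.max(gaps)]
  list(k = k, gaps = gaps, heights = h)
}

#' Assign a new station to an existing o-t-region
#'
#' Minimizes the Ward distance increase: joining cluster `c` of size `n_c`
#' raises the within-cluster sum of squares by
#' `n_c/(n_c+1) * ||x - centroid_c||^2`; the cluster with the smallest
#' increase wins (ties: smaller label).
#'
#' @param x feature vector (same construction/length as the training rows).
#' @param solution a `cluster_solution`.
#' @return integer region label.
#' @export
assign_region <- function(x, solution) {
  if (length(x) != ncol(solution$centroids))
    stop_otv("feature dimension mismatch", class = "input_error")
  d2 <- vapply(seq_len(solution$k), function(c) {
    nc <- solution$sizes[c]
    nc / (nc + 1) * sum((x - solution$centroids[c, ])^2)
  }, numeric(1))
  which.min(d2)  # which.min returns the first (smallest label) among ties
}

#' Representative stations per region and station type
#'
#' Within each region and each station type present (urban, suburban,
#' rural), picks the station whose feature vector is closest (Euclidean) to
#' the region centroid, then ranks the picks within the region by distance
#' (first/second/third representative).
#'
#' @param solution a `cluster_solution`.
#' @param features the feature matrix used for clustering.
#' @param metadata data frame with `station_id` and `station_type`.
#' @return data frame `region, rank, station_id, station_type, distance`.
#' @export
representative_stations <- function(solution, features, metadata) {
  out <- list()
  for (r in seq_len(solution$k)) {
    members <- names(solution$labels)[solution$labels == r]
    if (!length(members)) stop_otv("empty region ", r, class = "internal_error")
    ctr <- solution$centroids[r, ]
    md <- metadata[match(members, metadata$station_id), ]
    dist <- sqrt(rowSums((features[members, , drop = FALSE] -
                            matrix(ctr, length(members), length(ctr),
                                   byrow = TRUE))^2))
    picks <- do.call(rbind, lapply(split(seq_along(members), md$station_type),
                                   function(idx) {
      j <- idx[which.min(dist[idx])]
      data.frame(region = r, station_id = members[j],
                 station_type = md$station_type[j], distance = dist[j])
    }))
    picks <- picks[order(picks$distance), ]
    picks$rank <- seq_len(nrow(picks))
    out[[r]] <- picks
  }
  res <- do.call(rbind, out)[, c("region", "rank", "station_id",
                                 "station_type", "distance")]
  rownames(res) <- NULL
  res
}
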