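#' Standardize daily MSLP fields for weather typing
#'
#' Each grid cell is standardized over time (temporal mean 0, sd 1) and the
#' field is flattened row-major over (lat, lon). The per-cell parameters
#' are returned so the identical transform can be applied to new data
#' (e.g. bias-corrected ESM pressure fields).
#'
#' @param field a [grid_field()] of MSLP.
#' @return list of class `mslp_preprocess`: `vectors` (days x cells),
#'   `mean`, `sd` (per cell), `lat`, `lon`, `dates`.
#' @export
preprocess_mslp <- function(field) {
  m <- flatten_field(field)
  mu <- colMeans(m)
  sd_ <- apply(m, 2, stats::sd)
  if (any(sd_ == 0))
    stop_otv("zero-variance grid cell; cannot standardize",
             class = "preprocessing_error")
  v <- sweep(sweep(m, 2, mu), 2, sd_, "/")
  structure(list(vectors = v, mean = mu, sd = sd_, lat = field$lat,
                 lon = field$lon, dates = field$dates),
            class = "mslp_preprocess")
}

#' Apply stored MSLP preprocessing to a new field
#'
#' @param field a [grid_field()] on the same grid as training.
#' @param prep the `mslp_preprocess` object (or a `som_model`).
#' @return matrix of standardized day vectors.
#' @export
apply_mslp_preprocess <- function(field, prep) {
  mu <- prep$mean %||% prep$prep_mean
  sd_ <- prep$sd %||% prep$prep_sd
  m <- flatten_field(field)
  if (ncol(m) != length(mu))
    stop_otv("grid does not match preprocessing parameters",
             class = "input_error")
  sweep(sweep(m, 2, mu), 2, sd_, "/")
}

som_map_coords <- function(rows, cols) {
  cbind(row = rep(seq_len(rows), each = cols), col = rep(seq_len(cols), rows))
}

#' Train a self-organizing map on daily pressure vectors
#'
#' Online SOM with a Gaussian neighborhood on a rectangular grid. The
#' neighborhood radius `sigma` and the learning rate decay asymptotically
#' over iterations (`x / (1 + t / (iterations/2))`). Nodes are numbered
#' row-major, 1-based, so weather-type codes are stable given a seed.
#'
#' @param vectors matrix of standardized day vectors (days x cells).
#' @param shape integer `c(rows, cols)`; `rows*cols` nodes.
#' @param sigma initial neighborhood radius (map units).
#' @param learning_rate initial learning rate.
#' @param iterations number of single-sample updates.
#' @param seed RNG seed (weight initialization and sample order).
#' @param prep optional `mslp_preprocess` whose parameters are stored on
#'   the model for assigning raw fields later.
#' @return object of class `som_model`: `shape`, `weights`
#'   (nodes x cells), `sigma`, `learning_rate`, `iterations`, `seed`,
#'   `prep_mean`, `prep_sd`, and `qe_trace` (quantization error after each
#'   tenth of training).
#' @export
train_som <- function(vectors, shape, sigma = 1.0, learning_rate = 0.5,
                      iterations = 2000, seed = 1, prep = NULL) {
  rows <- shape[1]; cols <- shape[2]
  n_nodes <- rows * cols
  n <- nrow(vectors)
  if (n < 10 * n_nodes)
    stop_otv("need at least 10 training days per node",
             class = "training_error")
  set.seed(seed)
  w <- vectors[sample.int(n, n_nodes, replace = FALSE), , drop = FALSE]
  coords <- som_map_coords(rows, cols)
  half_life <- iterations / 2
  order_idx <- sample.int(n, iterations, replace = TRUE)
  checkpoints <- unique(round(seq(0.1, 1, by = 0.1) * iterations))
  qe_trace <- numeric(0)
  for (t in seq_len(iterations)) {
    x <- vectors[order_idx[t], ]
    diffs <- sweep(w, 2, x)
    bmu <- which.min(rowSums(diffs^2))
    sig_t <- sigma / (1 + (t - 1) / half_life)
    lr_t <- learning_rate / (1 + (t - 1) / half_life)
    d2map <- (coords[, 1] - coords[bmu, 1])^2 + (coords[, 2] - coords[bmu, 2])^2
    h <- lr_t * exp(-d2map / (2 * sig_t^2))
    w <- w - h * diffs
    if (t %in% checkpoints)
      qe_trace <- c(qe_trace, som_quantization_error_w(w, vectors))
  }
  structure(list(shape = c(rows = rows, cols = cols), weights = w,
                 sigma = sigma, learning_rate = learning_rate,
                 iterations = iterations, seed = seed,
                 prep_mean = prep$mean, prep_sd = prep$sd,
                 qe_trace = qe_trace, topographic_product = NULL),
            class = "som_model")
}

som_quantization_error_w <- function(w, vectors) {
  d2 <- outer(rowSums(vectors^2), rowSums(w^2), "+") -
    2 * vectors %*% t(w)
  mean(sqrt(pmax(apply(d2, 1, min), 0)))
}

#' Quantization error of a trained SOM
#'
#' Mean Euclidean distance between each day vector and its best-matching
#' node.
#'
#' @param model a `som_model`.
#' @param vectors day vectors (days x cells).
#' @return numeric scalar.
#' @export
som_quantization_error <- function(model, vectors) {
  som_quantization_error_w(model$weights, vectors)
}

#' Topographic product of a SOM
#'
#' Bauer-Pawelzik topology-preservation diagnostic. For every node `j` and
#' neighborhood order `k`, distances to the k-th nearest neighbor in weight
#' space and in map space are compared; the log-averaged combined ratio over
#' all nodes and orders is the topographic product. Values near 0 indicate
#' that the map's neighborhood structure matches data space; the sign
#' indicates whether the map dimension is too small (negative) or too large
#' (positive).
#'
#' @param model a `som_model` (or a list with `weights` and `shape`).
#' @return numeric scalar.
#' @export
topographic_product <- function(model) {
  w <- model$weights
  n <- nrow(w)
  if (n < 3) stop_otv("topographic product undefined for fewer than 3 nodes",
                      class = "input_error")
  coords <- som_map_coords(model$shape[1], model$shape[2])
  dV <- as.matrix(stats::dist(w))
  dA <- as.matrix(stats::dist(coords))
  total <- 0
  for (j in seq_len(n)) {
    others <- setdiff(seq_len(n), j)
    nV <- others[order(dV[j, others], others)]
    nA <- others[order(dA[j, others], others)]
    q1 <- dV[j, nA] / dV[j, nV]
    q2 <- dA[j, nA] / dA[j, nV]
    logp <- cumsum(log(q1) + log(q2)) / (2 * seq_len(n - 1))
    total <- total + sum(logp)
  }
  total / (n * (n - 1))
}

#' Select a SOM grid by the topographic product
#'
#' Trains every candidate grid shape at every hyperparameter combination
#' and returns the model with the smallest absolute topographic product,
#' together with the full leaderboard.
#'
#' @param vectors standardized day vectors.
#' @param shapes list of integer `c(rows, cols)` pairs; node counts should
#'   lie in the 4..20 range used for weather typing.
#' @param tuning data frame of hyperparameter combinations with columns
#'   `sigma`, `learning_rate`, `iterations` (a single-row default is used
#'   when omitted).
#' @param seed RNG seed shared by all trainings.
#' @param prep optional preprocessing parameters stored on each model.
#' @return list with `model` (best `som_model`, `topographic_product` set)
#'   and `leaderboard` (one row per shape x hyperparameter combination).
#' @export
select_som_grid <- function(vectors, shapes, tuning = NULL, seed = 1,
                            prep = NULL) {
  if (!length(shapes)) stop_otv("no candidate shapes",
                                class = "selection_error")
  tuning <- tuning %||% data.frame(sigma = 1.0, learning_rate = 0.5,
                                   iterations = 2000)
  rows <- list(); best <- NULL; best_tp <- Inf
  for (s in shapes) for (i in seq_len(nrow(tuning))) {
    m <- try(train_som(vectors, s, sigma = tuning$sigma[i],
                       learning_rate = tuning$learning_rate[i],
                       iterations = tuning$iterations[i], seed = seed,
                       prep = prep), silent = TRUE)
    if (inherits(m, "try-error")) next
    tp <- topographic_product(m)
    m$topographic_product <- tp
    rows[[length(rows) + 1]] <- data.frame(
      rows = s[1], cols = s[2], sigma = tuning$sigma[i],
      learning_rate = tuning$learning_rate[i],
      iterations = tuning$iterations[i], tp = tp,
      qe = som_quantization_error(m, vectors))
    if (abs(tp) < abs(best_tp)) { best <- m; best_tp <- tp }
  }
  if (is.null(best)) stop_otv("all SOM trainings failed",
                              class = "selection_error")
  list(model = best, leaderboard = do.call(rbind, rows))
}

#' Assign weather-type codes
#'
#' Each day receives the 1-based row-major index of its nearest node
#' (Euclidean distance in preprocessed space; ties take the lowest index).
#'
#' @param x a [grid_field()] of raw MSLP (standardized with the model's
#'   stored preprocessing parameters) or an already-standardized day-vector
#'   matrix.
#' @param model a `som_model`.
#' @return data frame `date` (if available) and `wt` (integer codes).
#' @export
assign_wt <- function(x, model) {
  if (inherits(x, "grid_field")) {
    dates <- x$dates
    v <- apply_mslp_preprocess(x, model)
  } else {
    dates <- attr(x, "dates")
    v <- x
  }
  if (ncol(v) != ncol(model$weights))
    stop_otv("vector dimension does not match SOM weights",
             class = "input_error")
  d2 <- outer(rowSums(v^2), rowSums(model$weights^2), "+") -
    2 * v %*% t(model$weights)
  wt <- apply(d2, 1, which.min)
  if (is.null(dates)) data.frame(wt = as.integer(wt)) else
    data.frame(date = dates, wt = as.integer(wt))
}
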