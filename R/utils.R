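#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_otv <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "otevents_error")))
}

#' Days of the year falling in given months
#'
#' @param years integer vector of calendar years.
#' @param months integer vector of months (1-12).
#' @return a `Date` vector, ordered, covering every day of `years` whose
#'   month is in `months` (leap days included).
#' @export
season_dates <- function(years, months = 4:9) {
  if (!length(years) || !length(months))
    stop_otv("empty year or month set", class = "configuration_error")
  d <- seq(as.Date(paste0(min(years), "-01-01")),
           as.Date(paste0(max(years), "-12-31")), by = "day")
  d <- d[as.integer(format(d, "%Y")) %in% years]
  d[as.integer(format(d, "%m")) %in% months]
}

all_dates <- function(years) {
  d <- seq(as.Date(paste0(min(years), "-01-01")),
           as.Date(paste0(max(years), "-12-31")), by = "day")
  d[as.integer(format(d, "%Y")) %in% years]
}

date_month <- function(dates) as.integer(format(dates, "%m"))
date_year  <- function(dates) as.integer(format(dates, "%Y"))
date_mmdd  <- function(dates) format(dates, "%m-%d")

#' Stratified cross-validation fold assignment
#'
#' Assigns each observation to one of `k` folds such that both outcome
#' classes are spread as evenly as possible across folds.
#'
#' @param y binary outcome vector (0/1).
#' @param k number of folds.
#' @return integer vector of fold ids in `1..k`.
#' @keywords internal
stratified_folds <- function(y, k) {
  if (min(table(y)) < k)
    stop_otv("each outcome class needs at least k = ", k,
             " members for stratified folds", class = "stratification_error")
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    f[idx] <- rep_len(seq_len(k), length(idx))
  }
  f
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to relabeling), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
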