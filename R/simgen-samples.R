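# Developmental periods, epochs and stages ------------------------------------
#
# The cohort model uses 12 discrete developmental periods spanning embryonic
# development through adolescence, grouped into four coarse epochs.  Periods
# 1-6 are prenatal, period 7 is the late-fetal transition, and periods 8-12
# are postnatal.

#' Epoch for a developmental period
#'
#' Maps periods 1-12 to epochs 0-3: epoch 0 = periods 1-2, epoch 1 = periods
#' 3-5, epoch 2 = periods 6-8 (the late-fetal transition), epoch 3 = periods
#' 9-12.
#'
#' @param period Integer vector of periods in 1..12.
#' @return Integer vector of epochs in 0..3.
#' @export
period_to_epoch <- function(period) {
  if (any(period < 1 | period > 12)) stopf("period must be in 1..12")
  e <- integer(length(period))
  e[period >= 3] <- 1L
  e[period >= 6] <- 2L
  e[period >= 9] <- 3L
  e
}

#' Stage (prenatal / transitional / postnatal) for a developmental period
#'
#' Periods 1-6 are prenatal, period 7 transitional, periods 8-12 postnatal.
#'
#' @param period Integer vector of periods in 1..12.
#' @return Character vector with values "prenatal", "transitional",
#'   "postnatal".
#' @export
period_to_stage <- function(period) {
  if (any(period < 1 | period > 12)) stopf("period must be in 1..12")
  ifelse(period <= 6, "prenatal",
         ifelse(period == 7, "transitional", "postnatal"))
}

#' Default per-period age intervals (post-conception days)
#'
#' Approximate boundaries for the 12 developmental periods, in days post
#' conception (1 post-conception week = 7 days, birth at ~280 days,
#' 1 year = 365 days).  Intervals are half-open, non-overlapping and ordered.
#'
#' @return A 12 x 2 matrix of (lower, upper) age bounds in days.
#' @export
default_age_ranges <- function() {
  m <- rbind(
    c(28,    56),    # period 1:  4-8 pcw
    c(56,    70),    # period 2:  8-10 pcw
    c(70,    91),    # period 3: 10-13 pcw
    c(91,   112),    # period 4: 13-16 pcw
    c(112,  133),    # period 5: 16-19 pcw
    c(133,  168),    # period 6: 19-24 pcw
    c(168,  280),    # period 7: 24 pcw - birth
    c(280,  447),    # period 8: birth - 6 months
    c(447,  632),    # period 9: 6-12 months
    c(632,  2457),   # period 10: 1-6 years
    c(2457, 4647),   # period 11: 6-12 years
    c(4647, 7572)    # period 12: 12-20 years
  )
  dimnames(m) <- list(paste0("period", 1:12), c("lo", "hi"))
  m
}

#' Default per-period sample counts
#'
#' 112 prenatal samples spread over periods 1-6, 4 transitional samples in
#' period 7, and 60 postnatal samples spread over periods 8-12, i.e. the
#' 176-sample developmental cohort layout the downstream eQTL cuts assume.
#'
#' @return Integer vector of length 12.
#' @export
default_n_per_period <- function() {
  c(8L, 18L, 30L, 28L, 18L, 10L, 4L, 12L, 12L, 12L, 12L, 12L)
}

#' Simulate a developmental sample table
#'
#' Generates a cohort with per-period sample counts, ages drawn uniformly
#' within per-period intervals, sexes Bernoulli(`p_male`), and five ancestry
#' principal components drawn i.i.d. standard normal.  Epoch and stage are
#' derived from period.
#'
#' @param n_per_period Integer vector of length 12; samples per period.
#' @param age_ranges 12 x 2 matrix of per-period (lower, upper) age bounds in
#'   post-conception days; intervals must be ordered and non-overlapping.
#' @param p_male Probability a sample is male (default 0.5).
#' @param n_pcs Number of ancestry principal components (default 5).
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `sample_id`, `age_days`, `period`,
#'   `epoch`, `sex`, `stage` and ancestry PC columns `pc1`..`pcN`.
#' @export
simulate_samples <- function(n_per_period = default_n_per_period(),
                             age_ranges = default_age_ranges(),
                             p_male = 0.5, n_pcs = 5L, seed = 1L) {
  if (length(n_per_period) != 12L) stopf("n_per_period must have length 12")
  if (any(n_per_period < 0)) stopf("n_per_period must be non-negative")
  if (sum(n_per_period) == 0L) stopf("empty cohort: all period counts are 0")
  if (!is.matrix(age_ranges) || nrow(age_ranges) != 12L ||
      ncol(age_ranges) != 2L)
    stopf("age_ranges must be a 12 x 2 matrix")
  if (any(age_ranges[, 1] >= age_ranges[, 2]))
    stopf("age_ranges intervals must have lower < upper")
  if (any(diff(as.vector(t(age_ranges))) < 0))
    stopf("age_ranges intervals must be ordered and non-overlapping")

  set.seed(seed)
  period <- rep(1:12, times = n_per_period)
  n <- length(period)
  age <- runif(n, age_ranges[period, 1], age_ranges[period, 2])
  tab <- data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    age_days = age,
    period = as.integer(period),
    epoch = period_to_epoch(period),
    sex = ifelse(rbinom(n, 1L, p_male) == 1L, "male", "female"),
    stage = period_to_stage(period),
    stringsAsFactors = FALSE
  )
  pcs <- matrix(rnorm(n * n_pcs), nrow = n,
                dimnames = list(NULL, paste0("pc", seq_len(n_pcs))))
  cbind(tab, as.data.frame(pcs))
}
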