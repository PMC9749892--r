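# Light attraction/avoidance preference analysis.

#' Per-bin light preference time series
#'
#' Preference is the percentage of activity in each environment over total
#' activity per 1-min bin: `percent_lit = 100 * lit / (lit + dark)` where
#' the bin has any activity, and undefined (`NA`) in zero-activity bins --
#' imputing 50/50 there would bias low-activity flies toward no-preference,
#' so undefined bins are excluded downstream instead.
#'
#' @param series a [choice_series()].
#' @return data.frame with `minute` (0-based, from ZT0), `lit`, `dark`,
#'   `total`, `percent_lit`, `percent_dark`; the two percentages sum to 100
#'   on every defined bin.
#' @export
preference_timeseries <- function(series) {
  stopifnot(inherits(series, "choice_series"))
  total <- series$lit_counts + series$dark_counts
  pct_lit <- ifelse(total > 0, 100 * series$lit_counts / total, NA_real_)
  data.frame(minute = seq_along(total) - 1,
             lit = series$lit_counts, dark = series$dark_counts,
             total = total,
             percent_lit = pct_lit,
             percent_dark = ifelse(total > 0, 100 - pct_lit, NA_real_))
}

#' Mean percent activity in the lit environment over an initial window
#'
#' Per fly, the mean of `percent_lit` over the defined bins of the first
#' `window_min` minutes (from ZT0); flies with no defined bin in the window
#' are excluded with a flag.  The cohort estimate is the mean +/- SEM across
#' the per-fly means (the per-fly mean is the statistical unit).
#'
#' @param cohort list of [choice_series()].
#' @param window_min analysis window length in minutes (default 30).
#' @return list with `per_fly` (data.frame: `fly_id`, `genotype`,
#'   `mean_percent_lit`, `n_defined_bins`, `excluded`), and cohort `mean`,
#'   `sem`, `n` over included flies.
#' @export
mean_percent_activity <- function(cohort, window_min = 30) {
  stopifnot(length(cohort) >= 1)
  n_bins <- length(cohort[[1]]$lit_counts)
  if (window_min > n_bins)
    stop(sprintf("window of %d min exceeds series length (%d min)",
                 window_min, n_bins), call. = FALSE)
  per_fly <- do.call(rbind, lapply(cohort, function(cs) {
    pref <- preference_timeseries(cs)
    w <- pref[pref$minute < window_min, ]
    def <- w$percent_lit[!is.na(w$percent_lit)]
    data.frame(fly_id = cs$fly_id, genotype = cs$genotype,
               mean_percent_lit = if (length(def)) mean(def) else NA_real_,
               n_defined_bins = length(def),
               excluded = length(def) == 0)
  }))
  vals <- per_fly$mean_percent_lit[!per_fly$excluded]
  list(per_fly = per_fly, mean = mean(vals), sem = sem(vals), n = length(vals))
}
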