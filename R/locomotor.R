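# Circadian locomotor analysis: chi-square (Sokolove-Bushell) periodogram,
# FaasX-style rhythmicity criteria, cohort summaries, anticipation indices,
# eduction profiles and actogram matrices.

#' Default period grid for the chi-square periodogram
#'
#' 16 to 32 h in 0.1-h steps.  Candidate periods are folded on integer bin
#' counts (nearest-bin rounding at 1-min resolution), so at 1-min bins each
#' 0.1-h step is 6 bins.
#'
#' @return numeric vector of candidate periods in hours.
#' @export
default_period_grid <- function() seq(16, 32, by = 0.1)

#' Rhythmicity scoring criteria
#'
#' The three scoring criteria used to call a fly rhythmic from its DD
#' periodogram: minimum power >= 20, minimum width >= 2 h, and a peak
#' exceeding the chi-square significance line at alpha = 0.05.  Boundary
#' values pass (the criteria are inclusive).
#'
#' @param min_power minimum peak power (Qp above the significance line).
#' @param min_width_h minimum contiguous supra-threshold span, hours.
#' @param alpha significance level of the chi-square line.
#' @return An object of class `rhythmicity_criteria`.
#' @export
rhythmicity_criteria <- function(min_power = 20, min_width_h = 2, alpha = 0.05) {
  check_number(min_power, "min_power", min = 0)
  check_number(min_width_h, "min_width_h", min = 0)
  check_number(alpha, "alpha", min = 0, max = 1, strict_min = TRUE, strict_max = TRUE)
  structure(list(min_power = min_power, min_width_h = min_width_h, alpha = alpha),
            class = "rhythmicity_criteria")
}

#' Chi-square (Sokolove-Bushell) periodogram
#'
#' For each candidate period of `P` bins the series is trimmed to
#' `K = floor(N/P)` complete cycles (the incomplete final cycle is dropped,
#' not wrapped) and folded; with column means `M_h`, grand mean `M` and
#' variance `sigma2 = mean((x - M)^2)` over the `K*P` retained bins, the
#' statistic is `Qp = K * sum((M_h - M)^2) / sigma2`, referred to the
#' chi-square quantile with `P - 1` degrees of freedom at level `alpha`.
#'
#' The peak period (tau) is the grid period maximizing `Qp - threshold`
#' among supra-threshold periods; `power` is that excess and `width_h` the
#' contiguous span of supra-threshold grid periods around the peak.  When no
#' period exceeds its line the result is non-significant and tau, power and
#' width are `NA`.  An all-constant series (zero variance) is returned as
#' non-significant with `degenerate = TRUE` rather than an error.
#'
#' @param series an [activity_series()].
#' @param dd_only if `TRUE` (default) and the schedule has a DD start, only
#'   constant-dark bins are analyzed.
#' @param period_grid_h candidate periods in hours; see
#'   [default_period_grid()].
#' @param alpha significance level of the chi-square line.
#' @return An object of class `periodogram_result` with fields `periods_h`,
#'   `qp`, `chi2_threshold`, `tau_h`, `power`, `width_h`, `significant`,
#'   `degenerate`, `alpha`, `n_bins_used`.
#' @export
chi_square_periodogram <- function(series, dd_only = TRUE,
                                   period_grid_h = default_period_grid(),
                                   alpha = 0.05) {
  stopifnot(inherits(series, "activity_series"))
  x <- series$counts
  if (dd_only && !is.na(series$schedule$dd_start_bin))
    x <- x[series$schedule$dd_start_bin:length(x)]
  x <- as.numeric(x)
  n <- length(x)
  bins_per_h <- 3600 / series$bin_seconds
  p_bins <- round(period_grid_h * bins_per_h)
  if (n < 2 * max(p_bins))
    stop(sprintf(paste("series too short for the period grid: %d bins available,",
                       "at least %d needed for 2 cycles at the longest period"),
                 n, 2 * max(p_bins)), call. = FALSE)

  qp <- numeric(length(p_bins))
  thr <- stats::qchisq(1 - alpha, df = p_bins - 1)
  degenerate <- FALSE
  for (j in seq_along(p_bins)) {
    P <- p_bins[j]
    K <- n %/% P
    xx <- x[seq_len(K * P)]
    m <- mean(xx)
    s2 <- mean((xx - m)^2)
    if (s2 == 0) { degenerate <- TRUE; qp[j] <- 0; next }
    col_means <- rowMeans(matrix(xx, nrow = P))
    qp[j] <- K * sum((col_means - m)^2) / s2
  }

  res <- list(periods_h = period_grid_h, qp = qp, chi2_threshold = thr,
              alpha = alpha, n_bins_used = n,
              tau_h = NA_real_, power = NA_real_, width_h = NA_real_,
              significant = FALSE, degenerate = degenerate)
  supra <- qp > thr
  if (!degenerate && any(supra)) {
    power <- qp - thr
    peak <- which(supra)[which.max(power[supra])]
    lo <- peak
    while (lo > 1 && supra[lo - 1]) lo <- lo - 1
    hi <- peak
    while (hi < length(supra) && supra[hi + 1]) hi <- hi + 1
    step <- if (length(period_grid_h) > 1) stats::median(diff(period_grid_h)) else 0.1
    res$significant <- TRUE
    res$tau_h <- period_grid_h[peak]
    res$power <- power[peak]
    res$width_h <- period_grid_h[hi] - period_grid_h[lo] + step
  }
  structure(res, class = "periodogram_result")
}

#' Classify a fly as rhythmic or arrhythmic
#'
#' Rhythmic iff the periodogram peak is significant AND power >= `min_power`
#' AND width >= `min_width_h`; boundary values pass.  Total function: never
#' errors.
#'
#' @param result a [chi_square_periodogram()] result.
#' @param criteria a [rhythmicity_criteria()].
#' @return list with `rhythmic` flag and `failed`, the character vector of
#'   failed criteria (among "significance", "power", "width"; empty when
#'   rhythmic).
#' @export
classify_rhythmic <- function(result, criteria = rhythmicity_criteria()) {
  failed <- character(0)
  if (!isTRUE(result$significant)) {
    failed <- "significance"
  } else {
    if (result$power < criteria$min_power) failed <- c(failed, "power")
    if (result$width_h < criteria$min_width_h) failed <- c(failed, "width")
  }
  list(rhythmic = length(failed) == 0, failed = failed)
}

#' Cohort rhythmicity summary
#'
#' Percent rhythmic and mean +/- SEM of tau, power and width over the
#' rhythmic flies only.  With zero rhythmic flies the means are `NA` and
#' percent is 0.
#'
#' @param results list of [chi_square_periodogram()] results.
#' @param criteria a [rhythmicity_criteria()].
#' @return An object of class `cohort_rhythmicity` (a list with `n`,
#'   `n_rhythmic`, `percent_rhythmic`, and `tau`/`power`/`width`
#'   `_mean`/`_sem` fields).
#' @export
cohort_summary <- function(results, criteria = rhythmicity_criteria()) {
  if (length(results) < 1) stop("at least one fly is required", call. = FALSE)
  calls <- vapply(results, function(r) classify_rhythmic(r, criteria)$rhythmic,
                  logical(1))
  rhythmic <- results[calls]
  grab <- function(field) vapply(rhythmic, `[[`, numeric(1), field)
  stat <- function(v) if (length(v)) c(mean(v), sem(v)) else c(NA_real_, NA_real_)
  tau <- stat(grab("tau_h")); pow <- stat(grab("power")); wid <- stat(grab("width_h"))
  structure(list(n = length(results), n_rhythmic = sum(calls),
                 percent_rhythmic = 100 * sum(calls) / length(results),
                 tau_mean = tau[1], tau_sem = tau[2],
                 power_mean = pow[1], power_sem = pow[2],
                 width_mean = wid[1], width_sem = wid[2]),
            class = "cohort_rhythmicity")
}

#' Anticipation index for a light transition
#'
#' For each LD day, AI = mean activity in the 3 h preceding the transition
#' divided by mean activity in the 6 h preceding it; both windows end at and
#' exclude the transition bin.  Days whose 6-h window has zero activity are
#' excluded; the per-day values are averaged over the last `n_days` usable
#' LD days.  For nonnegative counts AI lies in \[0, 2\]: 1 means no ramping,
#' 2 means all 6-h activity fell in the final 3 h.
#'
#' @param series an [activity_series()] starting at ZT0 with an LD segment.
#' @param transition `"morning"` (lights-on) or `"evening"` (lights-off).
#' @param n_days number of LD days to average over (default 5).
#' @return list with `fly_id`, `morning`/`evening` label, `ai` (NA when all
#'   days were excluded, with `all_excluded = TRUE`), `per_day` values and
#'   `days_used`.
#' @export
anticipation_index <- function(series, transition = c("morning", "evening"),
                               n_days = 5) {
  stopifnot(inherits(series, "activity_series"))
  transition <- match.arg(transition)
  sched <- series$schedule
  bins_per_day <- 1440L
  n <- length(series$counts)
  ld_end <- if (is.na(sched$dd_start_bin)) n else sched$dd_start_bin - 1L
  trans_offset <- if (transition == "morning") 0L else
    as.integer(round(sched$photoperiod * 60))
  # 0-based bin index of each candidate transition
  cand <- (0:((n %/% bins_per_day))) * bins_per_day + trans_offset
  # the transition must actually occur under LD (the LD->DD boundary has no
  # lights-on), and its full 6-h window must exist
  ok <- cand - 360 >= 0 & cand < ld_end & cand > 0
  cand <- cand[ok]
  if (length(cand) < n_days)
    stop(sprintf("only %d complete LD transitions available, %d days requested",
                 length(cand), n_days), call. = FALSE)
  cand <- utils::tail(cand, n_days)
  per_day <- vapply(cand, function(b) {
    w6 <- series$counts[(b - 360 + 1):b]       # [T-6h, T)
    w3 <- series$counts[(b - 180 + 1):b]       # [T-3h, T)
    if (sum(w6) == 0) NA_real_ else mean(w3) / mean(w6)
  }, numeric(1))
  used <- per_day[!is.na(per_day)]
  list(fly_id = series$fly_id, transition = transition,
       ai = if (length(used)) mean(used) else NA_real_,
       per_day = per_day, days_used = length(used),
       all_excluded = length(used) == 0)
}

#' Average daily activity profile (eduction)
#'
#' Mean activity per daily bin across complete days; a partial trailing day
#' is trimmed with a warning.
#'
#' @param series an [activity_series()].
#' @param days optional integer vector of (1-based) days to include.
#' @return numeric vector of length 1440 (bins of the averaged day).
#' @export
eduction <- function(series, days = NULL) {
  m <- actogram_matrix(series)
  if (!is.null(days)) m <- m[days, , drop = FALSE]
  colMeans(m)
}

#' Day-by-bin activity matrix for actogram display
#'
#' @param series an [activity_series()].
#' @param double_plot if `TRUE`, each row is day *i* followed by day
#'   *i + 1* (the conventional double-plotted actogram); the final row's
#'   second half is `NA`.
#' @return numeric matrix, days x 1440 (or days x 2880 when double-plotted).
#' @export
actogram_matrix <- function(series, double_plot = FALSE) {
  bins_per_day <- 1440L
  n_days <- length(series$counts) %/% bins_per_day
  if (n_days < 1) stop("series shorter than one day", call. = FALSE)
  if (length(series$counts) %% bins_per_day != 0)
    warning("partial trailing day trimmed", call. = FALSE)
  m <- matrix(series$counts[seq_len(n_days * bins_per_day)],
              nrow = n_days, byrow = TRUE)
  if (double_plot) {
    nxt <- rbind(m[-1, , drop = FALSE], rep(NA_real_, bins_per_day))
    m <- cbind(m, nxt)
  }
  m
}
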