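# Current-clamp light-response analysis: spike detection, firing-frequency
# ratios, sweep-averaged evoked potentials, basal metrics, tonic/burst
# classification.

sweep_voltages <- function(rec) {
  n_sweep <- round(sweep_duration_s(rec$protocol) * rec$sampling_hz)
  n_sweeps <- rec$protocol$n_sweeps
  matrix(rec$voltage_mv[seq_len(n_sweep * n_sweeps)], nrow = n_sweep)
}

#' Detect spikes in a voltage recording
#'
#' Per sweep, a running-median baseline (~25 ms window) is subtracted and a
#' spike is an upward crossing of `median + k * MAD` of the residual, with a
#' floor of `min_prominence_mv`; at most one event is kept per refractory
#' window and the spike time is the peak sample.  The MAD threshold adapts
#' to the noise level while the absolute floor keeps a noiseless flat trace
#' spike-free.
#'
#' @param rec a [voltage_recording()].
#' @param threshold_k MAD multiplier (default 6).
#' @param min_prominence_mv minimum absolute residual prominence (default 10 mV).
#' @param refractory_ms refractory period (default 2 ms).
#' @return list of [spike_train()], one per sweep.
#' @export
detect_spikes <- function(rec, threshold_k = 6, min_prominence_mv = 10,
                          refractory_ms = 2) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (length(rec$voltage_mv) == 0) stop("empty trace", call. = FALSE)
  fs <- rec$sampling_hz
  vm <- sweep_voltages(rec)
  k_med <- 2L * round(0.0125 * fs) + 1L     # ~25 ms, odd
  ref_n <- max(1L, round(refractory_ms / 1000 * fs))
  lapply(seq_len(ncol(vm)), function(s) {
    v <- vm[, s]
    r <- v - stats::runmed(v, k_med, endrule = "median")
    thr <- max(stats::median(r) + threshold_k * stats::mad(r), min_prominence_mv)
    above <- r > thr
    cross <- which(above & !c(FALSE, above[-length(above)]))
    times <- numeric(0)
    last <- -Inf
    for (i in cross) {
      j <- i + which.max(v[i:min(i + ref_n, length(v))]) - 1L
      tj <- (j - 1) / fs
      if (tj - last >= refractory_ms / 1000) {
        times <- c(times, tj)
        last <- tj
      }
    }
    spike_train(s, times)
  })
}

#' Firing-frequency summary for one cell
#'
#' Spike counts are pooled across the recording's sweeps.  The pre-stimulus
#' baseline is binned in five 10-s bins; the baseline rate is their mean.
#' The firing-frequency ratio is the stimulus-window rate (stimulus spike
#' count converted to Hz) divided by the baseline rate, so a stationary
#' train gives exactly 1.  The four 10-s post-stimulus bins (up to 40 s
#' after light-off) are reported as rates relative to baseline.  Cells with
#' zero baseline spikes have no defined ratio (`defined = FALSE`) and are
#' flagged for exclusion.
#'
#' @param spikes list of [spike_train()] (e.g. from [detect_spikes()]).
#' @param protocol the [sweep_protocol()] the trains were recorded under.
#' @return An object of class `firing_summary`: `baseline_bin_rates_hz` (5),
#'   `baseline_rate_hz`, `stim_rate_hz`, `ff_ratio`, `post_ratios` (4),
#'   `defined`.
#' @export
firing_frequency_ratio <- function(spikes, protocol) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  times <- unlist(lapply(spikes, `[[`, "spike_times_s"))
  n_sw <- protocol$n_sweeps
  pre <- protocol$pre_dark_s
  stim <- protocol$stim_s
  count_in <- function(a, b) sum(times >= a & times < b)
  base_edges <- seq(0, pre, by = 10)
  base_counts <- vapply(seq_len(length(base_edges) - 1), function(i)
    count_in(base_edges[i], base_edges[i + 1]), numeric(1))
  base_rates <- base_counts / (10 * n_sw)
  baseline <- mean(base_rates)
  stim_rate <- count_in(pre, pre + stim) / (stim * n_sw)
  post_edges <- pre + stim + seq(0, 40, by = 10)
  post_rates <- vapply(seq_len(4), function(i)
    count_in(post_edges[i], post_edges[i + 1]), numeric(1)) / (10 * n_sw)
  defined <- baseline > 0
  structure(list(baseline_bin_rates_hz = base_rates,
                 baseline_rate_hz = baseline,
                 stim_rate_hz = stim_rate,
                 ff_ratio = if (defined) stim_rate / baseline else NA_real_,
                 post_ratios = if (defined) post_rates / baseline else
                   rep(NA_real_, 4),
                 defined = defined),
            class = "firing_summary")
}

#' Gaussian smoothing followed by zero-phase Butterworth low-pass
#'
#' The low-pass stage of the evoked-potential pipeline, exposed for direct
#' use: a normalized Gaussian kernel (so DC gain is exactly 1) followed by a
#' zero-phase (forward-backward) Butterworth filter.  Edges are handled by
#' constant padding, which keeps a constant input constant.
#'
#' @param x numeric signal.
#' @param fs sampling rate, Hz.
#' @param gaussian_sigma_ms Gaussian kernel sigma (0 skips the stage).
#' @param butter_order,butter_cutoff_hz Butterworth design; the cutoff must
#'   be below the Nyquist frequency.
#' @return filtered signal, same length as `x`.
#' @export
smooth_lowpass <- function(x, fs, gaussian_sigma_ms = 50,
                           butter_order = 3, butter_cutoff_hz = 2) {
  if (butter_cutoff_hz >= fs / 2)
    stop("Butterworth cutoff must be below the Nyquist frequency", call. = FALSE)
  sig_n <- gaussian_sigma_ms / 1000 * fs
  half <- if (sig_n > 0) ceiling(4 * sig_n) else 0L
  pad <- half + ceiling(2.5 * fs / butter_cutoff_hz)
  xp <- c(rep(x[1], pad), x, rep(x[length(x)], pad))
  if (sig_n > 0) {
    kern <- stats::dnorm(seq(-half, half), sd = sig_n)
    kern <- kern / sum(kern)
    sm <- stats::filter(xp, kern, sides = 2)
    sm[is.na(sm)] <- xp[is.na(sm)]     # constant-padded edges
    xp <- as.numeric(sm)
  }
  bf <- signal::butter(butter_order, butter_cutoff_hz / (fs / 2), type = "low")
  # filter around the signal mean: startup transients scale with the
  # deviation from it, so a constant input passes exactly (DC gain 1)
  mu <- mean(xp)
  xf <- signal::filtfilt(bf, xp - mu) + mu
  xf[(pad + 1):(pad + length(x))]
}

#' Averaged, baseline-adjusted, low-pass-filtered evoked potential
#'
#' Sweeps are aligned on stimulus onset and averaged pointwise; the mean of
#' the final `baseline_window_s` seconds before the stimulus is subtracted;
#' the result is Gaussian-smoothed then zero-phase Butterworth low-pass
#' filtered (see [smooth_lowpass()]).  After filtering, the pre-pulse
#' baseline mean is re-zeroed so it is exactly 0.  The last 60 s of the
#' averaged sweep are also returned for figure-style summaries.
#'
#' @param rec a [voltage_recording()] with at least one complete sweep.
#' @param baseline_window_s pre-pulse baseline window (default final 10 s of
#'   the dark period).
#' @param gaussian_sigma_ms,butter_order,butter_cutoff_hz filter settings.
#' @return An object of class `evoked_potential`: `time_s`, `delta_mv`,
#'   `n_sweeps`, `filter_settings`, `baseline_idx`, and `last60` (time and
#'   delta over the final 60 s of the sweep).
#' @export
evoked_potential <- function(rec, baseline_window_s = 10,
                             gaussian_sigma_ms = 50, butter_order = 3,
                             butter_cutoff_hz = 2) {
  stopifnot(inherits(rec, "voltage_recording"))
  p <- rec$protocol
  if (p$n_sweeps < 1) stop("no sweeps", call. = FALSE)
  fs <- rec$sampling_hz
  avg <- rowMeans(sweep_voltages(rec))
  bidx <- (round((p$pre_dark_s - baseline_window_s) * fs) + 1):round(p$pre_dark_s * fs)
  d <- avg - mean(avg[bidx])
  f <- smooth_lowpass(d, fs, gaussian_sigma_ms, butter_order, butter_cutoff_hz)
  f <- f - mean(f[bidx])
  t <- (seq_along(f) - 1) / fs
  last_idx <- t >= sweep_duration_s(p) - 60
  structure(list(time_s = t, delta_mv = f, n_sweeps = p$n_sweeps,
                 filter_settings = list(baseline_window_s = baseline_window_s,
                                        gaussian_sigma_ms = gaussian_sigma_ms,
                                        butter_order = butter_order,
                                        butter_cutoff_hz = butter_cutoff_hz),
                 baseline_idx = bidx,
                 last60 = list(time_s = t[last_idx], delta_mv = f[last_idx])),
            class = "evoked_potential")
}

#' Basal (pre-stimulus) cell metrics
#'
#' Resting membrane potential is the mode of the 1-mV voltage histogram over
#' spike-blanked pre-stimulus data (the mean of samples in the modal bin, so
#' a noiseless trace recovers its value exactly); the basal firing rate is
#' the pooled pre-stimulus spike count divided by total pre-stimulus time.
#' Firing mode comes from [classify_firing_mode()] on the pre-stimulus
#' spikes.  A warning is issued for an implausible nonnegative RMP.
#'
#' @param rec a [voltage_recording()].
#' @param spikes optional precomputed spike trains; detected if missing.
#' @param blank_ms half-width of the window blanked around each spike.
#' @return An object of class `cell_basal`: `cell_id`, `genotype`, `rmp_mv`,
#'   `basal_rate_hz`, `firing_mode`, `zt_of_recording`.
#' @export
basal_metrics <- function(rec, spikes = NULL, blank_ms = 5) {
  stopifnot(inherits(rec, "voltage_recording"))
  if (is.null(spikes)) spikes <- detect_spikes(rec)
  fs <- rec$sampling_hz
  pre_n <- round(rec$protocol$pre_dark_s * fs)
  vm <- sweep_voltages(rec)
  blank_n <- round(blank_ms / 1000 * fs)
  pooled <- unlist(lapply(seq_len(ncol(vm)), function(s) {
    v <- vm[seq_len(pre_n), s]
    st <- spikes[[s]]$spike_times_s
    st <- st[st < rec$protocol$pre_dark_s]
    keep <- rep(TRUE, pre_n)
    for (ts in st) {
      i <- round(ts * fs) + 1
      keep[max(1, i - blank_n):min(pre_n, i + blank_n)] <- FALSE
    }
    v[keep]
  }))
  if (length(pooled) == 0) stop("all pre-stimulus samples blanked", call. = FALSE)
  bin <- round(pooled)                       # 1-mV bins centered on integers
  modal <- as.numeric(names(which.max(table(bin))))
  rmp <- mean(pooled[bin == modal])
  if (!is.na(rmp) && rmp >= 0)
    warning("nonnegative resting membrane potential; check the recording",
            call. = FALSE)
  pre_spikes <- lapply(spikes, function(tr)
    spike_train(tr$sweep_index,
                tr$spike_times_s[tr$spike_times_s < rec$protocol$pre_dark_s]))
  n_pre <- sum(vapply(pre_spikes, function(tr) length(tr$spike_times_s), numeric(1)))
  structure(list(cell_id = rec$cell_id, genotype = rec$genotype,
                 rmp_mv = rmp,
                 basal_rate_hz = n_pre / (rec$protocol$pre_dark_s * ncol(vm)),
                 firing_mode = classify_firing_mode(pre_spikes),
                 zt_of_recording = rec$zt_of_recording),
            class = "cell_basal")
}

#' Classify tonic vs. burst firing
#'
#' Spikes are grouped (per sweep) into maximal runs with inter-spike
#' intervals at most `max_isi_s`; a run qualifies as a burst when it has at
#' least `min_run` spikes and is separated from neighboring spikes by gaps
#' of at least `min_gap_s`.  The cell is `"burst"` when at least half of all
#' spikes lie in bursts, `"tonic"` otherwise, and `"unclassified"` with
#' fewer than `min_spikes` spikes.
#'
#' @param spikes list of [spike_train()].
#' @param max_isi_s intra-burst inter-spike interval bound (default 0.1 s).
#' @param min_run minimum spikes per burst (default 3).
#' @param min_gap_s minimum silent gap flanking a burst (default 0.3 s).
#' @param min_spikes minimum spike count to attempt classification.
#' @return `"tonic"`, `"burst"` or `"unclassified"`.
#' @export
classify_firing_mode <- function(spikes, max_isi_s = 0.1, min_run = 3,
                                 min_gap_s = 0.3, min_spikes = 10) {
  per_sweep <- lapply(spikes, `[[`, "spike_times_s")
  total <- sum(lengths(per_sweep))
  if (total < min_spikes) return("unclassified")
  in_burst <- 0
  for (tt in per_sweep) {
    if (length(tt) == 0) next
    grp <- cumsum(c(TRUE, diff(tt) > max_isi_s))
    for (g in unique(grp)) {
      idx <- which(grp == g)
      if (length(idx) < min_run) next
      gap_before <- if (min(idx) == 1) Inf else tt[min(idx)] - tt[min(idx) - 1]
      gap_after <- if (max(idx) == length(tt)) Inf else tt[max(idx) + 1] - tt[max(idx)]
      if (gap_before >= min_gap_s && gap_after >= min_gap_s)
        in_burst <- in_burst + length(idx)
    }
  }
  if (in_burst / total >= 0.5) "burst" else "tonic"
}
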