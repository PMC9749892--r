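# Synthetic-data generators for the four assays.  Each generator takes one
# explicit seed, leaves the caller's RNG untouched, and attaches its latent
# parameters/events as a "ground_truth" attribute so downstream stages can be
# tested by parameter recovery.

# Daily activity profile on the ZT circle, in [0, 1]: two raised-cosine lobes
# centered at lights-on (ZT0) and lights-off (ZT `photoperiod`) plus
# exponential ramps rising over `ramp_h` hours before each transition.
activity_profile <- function(zt, photoperiod = 12, ramp_h = 3, lobe_halfwidth_h = 4) {
  lobe <- function(zt, center) {
    d <- abs(((zt - center + 12) %% 24) - 12)
    ifelse(d <= lobe_halfwidth_h, 0.5 * (1 + cos(pi * d / lobe_halfwidth_h)), 0)
  }
  ramp <- function(zt, center) {
    if (ramp_h <= 0) return(rep(0, length(zt)))
    d <- (center - zt) %% 24
    ifelse(d > 0 & d <= ramp_h, exp(-3 * d / ramp_h), 0)
  }
  raw <- lobe(zt, 0) + lobe(zt, photoperiod) +
    ramp(zt, 0) + ramp(zt, photoperiod)
  ref <- seq(0, 24, by = 0.002)
  raw_ref <- lobe(ref, 0) + lobe(ref, photoperiod) +
    ramp(ref, 0) + ramp(ref, photoperiod)
  raw / max(raw_ref)
}

#' Simulate a locomotor activity cohort
#'
#' Draws per-minute beam-crossing counts for `n_flies` flies from an
#' inhomogeneous Poisson process with rate
#' `base_rate * (1 + amplitude * s(phase))`, clipped at zero, where `s` is a
#' bimodal daily profile with morning/evening lobes and exponential
#' anticipation ramps (see [activity_profile()]).  During LD the phase
#' follows Zeitgeber time; from the first DD bin it free-runs with period
#' `tau_h`.  A `(1 - rhythmic_fraction)` tail of the cohort is generated
#' with amplitude 0 (arrhythmic).
#'
#' @param preset a [genotype_preset()]; the `locomotor` block is used.
#' @param n_flies cohort size.
#' @param days_ld,days_dd whole days of LD entrainment and constant darkness;
#'   either may be 0 but not both.
#' @param lux white-light intensity recorded in the schedule (metadata).
#' @param seed integer seed; identical calls are bit-identical.
#' @return List of [activity_series()], with attribute `ground_truth`: a
#'   data.frame of each fly's latent `rhythmic` flag and `tau_h`.
#' @export
simulate_locomotor <- function(preset, n_flies, days_ld, days_dd,
                               lux = 400, seed) {
  loc <- preset$locomotor
  n_flies <- check_count(n_flies, "n_flies")
  days_ld <- check_count(days_ld, "days_ld", min = 0)
  days_dd <- check_count(days_dd, "days_dd", min = 0)
  if (days_ld + days_dd < 1)
    stop_field("days_ld + days_dd", "must be at least 1 day")

  n_bins <- (days_ld + days_dd) * 1440L
  h <- (seq_len(n_bins) - 0.5) / 60               # bin midpoints, hours
  dd_start_h <- days_ld * 24
  in_dd <- h >= dd_start_h
  phase <- ifelse(in_dd,
                  (dd_start_h + (h - dd_start_h) * 24 / loc$tau_h) %% 24,
                  h %% 24)
  s <- activity_profile(phase, photoperiod = 12,
                        ramp_h = loc$anticipation_ramp_h)
  schedule <- light_schedule(lux = lux,
                             dd_start_bin = if (days_dd > 0) days_ld * 1440L + 1L else NA)
  n_rhythmic <- round(loc$rhythmic_fraction * n_flies)

  flies <- with_seed(seed, {
    lapply(seq_len(n_flies), function(i) {
      amp <- if (i <= n_rhythmic) loc$amplitude else 0
      rate <- pmax(0, loc$base_rate * (1 + amp * s))
      activity_series(fly_id = sprintf("%s_fly%02d", preset$name, i),
                      genotype = preset$name,
                      counts = stats::rpois(n_bins, rate),
                      schedule = schedule)
    })
  })
  attr(flies, "ground_truth") <- data.frame(
    fly_id = vapply(flies, function(f) f$fly_id, character(1)),
    rhythmic = seq_len(n_flies) <= n_rhythmic,
    tau_h = loc$tau_h, base_rate = loc$base_rate,
    amplitude = ifelse(seq_len(n_flies) <= n_rhythmic, loc$amplitude, 0))
  flies
}

# biphasic spike template: 1 ms rise-fall to `amp_up` above baseline, then a
# 1 ms undershoot of 15% of the upstroke
spike_template <- function(sampling_hz, amp_up) {
  half <- round(0.001 * sampling_hz)
  if (half < 2)
    stop("sampling rate too low to render the 2-ms spike template", call. = FALSE)
  c(amp_up * sin(pi * seq_len(half) / (half + 1)),
    -0.15 * amp_up * sin(pi * seq_len(half) / (half + 1)))
}

# inhomogeneous Poisson event times on [0, t_end) by thinning
poisson_times <- function(rate_fn, rate_max, t_end) {
  if (rate_max <= 0) return(numeric(0))
  n_cand <- stats::rpois(1, rate_max * t_end)
  cand <- sort(stats::runif(n_cand, 0, t_end))
  cand[stats::runif(n_cand) < rate_fn(cand) / rate_max]
}

#' Simulate a light-evoked current-clamp recording
#'
#' Generates a multi-sweep membrane-voltage trace under the dark / light /
#' dark sweep protocol.  Per sweep the voltage is
#' `rmp + D(t) + spikes + noise`, with light-evoked depolarization
#' `D(t) = A (1 - exp(-t/tau_on))` during the stimulus and exponential decay
#' with `tau_off` after it.  Spikes come from an inhomogeneous Poisson
#' process with rate `basal_rate_hz + gain * D(t)` (burst presets place
#' triplets with 50-ms intra-burst intervals at Poisson onsets) and are
#' rendered as a fixed biphasic 2-ms template whose peak reaches about
#' +60 mV.
#'
#' @param preset a [genotype_preset()]; the `ephys` block is used.
#' @param protocol a [sweep_protocol()].
#' @param sampling_hz sampling rate (>= 2000 Hz).
#' @param seed integer seed.
#' @param cell_id,zt_of_recording labels carried into the recording.
#' @return A [voltage_recording()] with attribute `ground_truth`: list with
#'   per-sweep true spike times (`spike_times`), the noiseless
#'   depolarization trace of one sweep (`depolarization_mv`), and the preset
#'   parameters (`params`).
#' @export
simulate_voltage <- function(preset, protocol = sweep_protocol(),
                             sampling_hz = 2000, seed,
                             cell_id = paste0(preset$name, "_cell"),
                             zt_of_recording = NA) {
  e <- preset$ephys
  check_number(sampling_hz, "sampling_hz", min = 2000)
  sweep_s <- sweep_duration_s(protocol)
  n_sweep <- round(sweep_s * sampling_hz)
  t <- (seq_len(n_sweep) - 1) / sampling_hz
  stim_on <- protocol$pre_dark_s
  stim_off <- protocol$pre_dark_s + protocol$stim_s
  a_end <- e$depol_amplitude_mv * (1 - exp(-protocol$stim_s / e$tau_on_s))
  depol <- function(tt) {
    ifelse(tt < stim_on, 0,
           ifelse(tt < stim_off,
                  e$depol_amplitude_mv * (1 - exp(-(tt - stim_on) / e$tau_on_s)),
                  a_end * exp(-(tt - stim_off) / e$tau_off_s)))
  }
  rate_fn <- function(tt) pmax(0, e$basal_rate_hz + e$gain_hz_per_mv * depol(tt))
  rate_max <- e$basal_rate_hz + max(0, e$gain_hz_per_mv * a_end) + 1e-9
  tpl <- spike_template(sampling_hz, amp_up = 60 - e$rmp_mv)
  d_trace <- depol(t)

  sim <- with_seed(seed, {
    lapply(seq_len(protocol$n_sweeps), function(s) {
      times <- if (isTRUE(e$burst)) {
        onsets <- poisson_times(function(tt) rate_fn(tt) / 3, rate_max / 3, sweep_s)
        sort(c(onsets, onsets + 0.05, onsets + 0.10))
      } else {
        poisson_times(rate_fn, rate_max, sweep_s)
      }
      times <- times[times < sweep_s - 0.002]
      # enforce a 2-ms refractory period
      if (length(times) > 1) {
        keep <- c(TRUE, diff(times) >= 0.002)
        while (!all(keep)) {
          times <- times[keep]
          keep <- c(TRUE, diff(times) >= 0.002)
        }
      }
      v <- e$rmp_mv + d_trace +
        (if (e$noise_sd_mv > 0) stats::rnorm(n_sweep, 0, e$noise_sd_mv) else 0)
      for (ts in times) {
        i0 <- round(ts * sampling_hz) + 1
        idx <- i0:min(i0 + length(tpl) - 1, n_sweep)
        v[idx] <- v[idx] + tpl[seq_along(idx)]
      }
      list(v = v, times = times)
    })
  })

  rec <- voltage_recording(cell_id = cell_id, genotype = preset$name,
                           voltage_mv = unlist(lapply(sim, `[[`, "v")),
                           sampling_hz = sampling_hz, protocol = protocol,
                           zt_of_recording = zt_of_recording)
  attr(rec, "ground_truth") <- list(
    spike_times = lapply(sim, `[[`, "times"),
    depolarization_mv = d_trace,
    params = e)
  rec
}

#' Simulate a light-choice cohort
#'
#' Per fly and per 1-min bin, total crossings are Poisson with mean
#' `total_rate` and the lit-side share is Binomial with the preset's
#' (possibly time-varying) probability `p_lit(minute)`; minutes are counted
#' from 0 at assay start (ZT0).  Lit + dark = total in every bin by
#' construction.
#'
#' @param preset a [genotype_preset()]; the `choice` block is used.
#' @param n_flies cohort size.
#' @param minutes number of 1-min bins.
#' @param seed integer seed.
#' @param wavelength_nm,intensity_uw_cm2 metadata for the series.
#' @return List of [choice_series()] with attribute `ground_truth` holding
#'   the per-bin `p_lit` used.
#' @export
simulate_choice <- function(preset, n_flies, minutes, seed,
                            wavelength_nm = 450, intensity_uw_cm2 = 10) {
  ch <- preset$choice
  n_flies <- check_count(n_flies, "n_flies")
  minutes <- check_count(minutes, "minutes")
  p <- ch$p_lit(seq_len(minutes) - 1)
  if (length(p) != minutes || any(!is.finite(p)) || any(p < 0 | p > 1))
    stop_field("choice$p_lit", "must return probabilities in [0, 1], one per minute")
  flies <- with_seed(seed, {
    lapply(seq_len(n_flies), function(i) {
      total <- stats::rpois(minutes, ch$total_rate)
      lit <- stats::rbinom(minutes, total, p)
      choice_series(fly_id = sprintf("%s_fly%02d", preset$name, i),
                    genotype = preset$name,
                    lit_counts = lit, dark_counts = total - lit,
                    wavelength_nm = wavelength_nm,
                    intensity_uw_cm2 = intensity_uw_cm2)
    })
  })
  attr(flies, "ground_truth") <- list(p_lit = p, total_rate = ch$total_rate)
  flies
}

#' Simulate an ROI fluorescence table
#'
#' One row per neuron.  Each brain draws a background intensity around
#' `background_mean` and each neuron a mean intensity around
#' `mean_by_zt[zt]`, both with multiplicative lognormal noise of
#' coefficient of variation `noise_cv` (exact means; `noise_cv = 0`
#' degenerates to the preset values so normalized intensities are exact).
#'
#' @param preset a [genotype_preset()]; the `icc` block is used.
#' @param n_brains,neurons_per_brain table dimensions.
#' @param zt Zeitgeber time point; must be a key of the preset's `mean_by_zt`.
#' @param seed integer seed.
#' @param channel `"TIM"` or `"GFP"`.
#' @return A validated ROI data.frame (see [validate_roi_table()]) with
#'   attribute `ground_truth` holding the preset means.
#' @export
simulate_roi <- function(preset, n_brains, neurons_per_brain, zt, seed,
                         channel = "TIM") {
  ic <- preset$icc
  n_brains <- check_count(n_brains, "n_brains")
  neurons_per_brain <- check_count(neurons_per_brain, "neurons_per_brain")
  key <- as.character(zt)
  if (!key %in% names(ic$mean_by_zt))
    stop_field("zt", sprintf("= %s is not a time point of this preset (has: %s)",
                             key, paste(names(ic$mean_by_zt), collapse = ", ")))
  tab <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_brains), function(b) {
      bg <- rlnorm_mean_cv(1, ic$background_mean, ic$noise_cv)
      data.frame(
        brain_id = sprintf("%s_zt%s_brain%02d", preset$name, key, b),
        neuron_id = sprintf("n%02d", seq_len(neurons_per_brain)),
        channel = channel,
        mean_intensity = rlnorm_mean_cv(neurons_per_brain,
                                        ic$mean_by_zt[[key]], ic$noise_cv),
        background_intensity = bg,
        zt = as.numeric(zt),
        genotype = preset$name)
    }))
  })
  tab <- validate_roi_table(tab)
  attr(tab, "ground_truth") <- list(mean_intensity = ic$mean_by_zt[[key]],
                                    background_mean = ic$background_mean,
                                    noise_cv = ic$noise_cv)
  tab
}
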