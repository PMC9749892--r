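#' Light schedule for an activity recording
#'
#' Describes the light regime a fly experienced: time of lights-on, the
#' photoperiod of the LD cycle, white-light intensity, and (optionally) the
#' first recording bin of constant darkness.  The Zeitgeber convention is
#' ZT0 = lights-on; ZT is carried in decimal hours throughout the package.
#'
#' @param zt0_clock_time clock time of lights-on in hours (metadata only).
#' @param photoperiod hours of light per 24 h day; must lie in (0, 24).
#'   Default 12 (a 12:12 LD cycle).
#' @param lux white-light intensity during the light phase (1 or 400 in the
#'   standard assay; any positive value is accepted).
#' @param dd_start_bin 1-based index of the first constant-dark bin, or `NA`
#'   if the whole recording is under LD.
#' @return An object of class `light_schedule`.
#' @export
light_schedule <- function(zt0_clock_time = 8, photoperiod = 12, lux = 400,
                           dd_start_bin = NA) {
  check_number(photoperiod, "photoperiod", min = 0, max = 24,
               strict_min = TRUE, strict_max = TRUE)
  check_number(lux, "lux", min = 0)
  if (!is.na(dd_start_bin)) dd_start_bin <- check_count(dd_start_bin, "dd_start_bin")
  structure(list(zt0_clock_time = zt0_clock_time, photoperiod = photoperiod,
                 lux = lux, dd_start_bin = dd_start_bin),
            class = "light_schedule")
}

#' One fly's beam-crossing activity series
#'
#' Per-minute beam-crossing counts from a DAM-style monitor, together with
#' the light schedule under which they were recorded.  Bins are half-open
#' `[t, t + 60 s)`; bin 1 starts at ZT0 of the first recording day.
#'
#' @param fly_id,genotype labels.
#' @param counts nonnegative integer vector, one count per 1-min bin.
#' @param schedule a [light_schedule()].
#' @param t0 start time of bin 1, in minutes from ZT0 of day 1 (0 = the
#'   recording starts at lights-on).
#' @param bin_seconds bin width; the DAM assay records 1-min bins.
#' @return An object of class `activity_series`.
#' @export
activity_series <- function(fly_id, genotype, counts, schedule,
                            t0 = 0, bin_seconds = 60) {
  if (!is_nonneg_int_vector(counts))
    stop_field("counts", "must be nonnegative integers")
  if (!inherits(schedule, "light_schedule"))
    stop_field("schedule", "must be a light_schedule")
  if (!is.na(schedule$dd_start_bin) && schedule$dd_start_bin > length(counts) + 1)
    stop_field("schedule$dd_start_bin", "lies beyond the series length")
  structure(list(fly_id = as.character(fly_id), genotype = as.character(genotype),
                 t0 = t0, bin_seconds = bin_seconds,
                 counts = as.integer(counts), schedule = schedule),
            class = "activity_series")
}

#' Light-stimulation sweep protocol
#'
#' The repeated light-pulse protocol used for whole-cell current-clamp
#' recordings: darkness for a baseline, a brief colored-light pulse, then
#' inter-pulse darkness, repeated over several sweeps.  Defaults are the
#' standard 50 s / 5 s / 95 s protocol repeated five times at 200 uW/cm2.
#'
#' @param pre_dark_s,stim_s,post_s segment durations in seconds.
#' @param n_sweeps number of sweeps per recording.
#' @param wavelength_nm LED peak wavelength (365, 405, 450 or 635).
#' @param intensity_uw_cm2 stimulus intensity in uW/cm2.
#' @return An object of class `sweep_protocol`.
#' @export
sweep_protocol <- function(pre_dark_s = 50, stim_s = 5, post_s = 95,
                           n_sweeps = 5, wavelength_nm = 450,
                           intensity_uw_cm2 = 200) {
  check_number(pre_dark_s, "pre_dark_s", min = 0, strict_min = TRUE)
  check_number(stim_s, "stim_s", min = 0, strict_min = TRUE)
  check_number(post_s, "post_s", min = 0, strict_min = TRUE)
  n_sweeps <- check_count(n_sweeps, "n_sweeps")
  structure(list(pre_dark_s = pre_dark_s, stim_s = stim_s, post_s = post_s,
                 n_sweeps = n_sweeps, wavelength_nm = wavelength_nm,
                 intensity_uw_cm2 = intensity_uw_cm2),
            class = "sweep_protocol")
}

sweep_duration_s <- function(protocol) {
  protocol$pre_dark_s + protocol$stim_s + protocol$post_s
}

#' Multi-sweep current-clamp voltage recording
#'
#' @param cell_id,genotype labels.
#' @param voltage_mv membrane voltage samples (mV), sweeps concatenated.
#' @param sampling_hz sampling rate; must be at least 2000 Hz.
#' @param protocol a [sweep_protocol()].
#' @param zt_of_recording Zeitgeber time of the recording (decimal hours) or `NA`.
#' @return An object of class `voltage_recording`.
#' @export
voltage_recording <- function(cell_id, genotype, voltage_mv, sampling_hz,
                              protocol, zt_of_recording = NA) {
  check_number(sampling_hz, "sampling_hz", min = 2000)
  if (!inherits(protocol, "sweep_protocol"))
    stop_field("protocol", "must be a sweep_protocol")
  expected <- protocol$n_sweeps * sweep_duration_s(protocol) * sampling_hz
  if (abs(length(voltage_mv) - expected) > 1)
    stop_field("voltage_mv", sprintf(
      "length %d does not match protocol (expected %d samples within one)",
      length(voltage_mv), round(expected)))
  structure(list(cell_id = as.character(cell_id), genotype = as.character(genotype),
                 zt_of_recording = zt_of_recording, sampling_hz = sampling_hz,
                 voltage_mv = as.numeric(voltage_mv), protocol = protocol),
            class = "voltage_recording")
}

#' Spike train for one sweep
#'
#' @param sweep_index 1-based sweep number.
#' @param spike_times_s strictly increasing spike times (s) within the sweep.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(sweep_index, spike_times_s) {
  if (length(spike_times_s) > 1 && any(diff(spike_times_s) <= 0))
    stop_field("spike_times_s", "must be strictly increasing")
  structure(list(sweep_index = as.integer(sweep_index),
                 spike_times_s = as.numeric(spike_times_s)),
            class = "spike_train")
}

#' Two-environment choice series for one fly
#'
#' Per-minute beam-crossing counts split between a lit and a dark
#' environment in the light attraction/avoidance assay.
#'
#' @param fly_id,genotype labels.
#' @param lit_counts,dark_counts nonnegative integer vectors of equal length.
#' @param wavelength_nm LED wavelength of the lit environment.
#' @param intensity_uw_cm2 light intensity (10 or 400 uW/cm2 in the assay).
#' @param bin_seconds bin width (60 s).
#' @return An object of class `choice_series`; the `inactive` field flags
#'   flies with no activity at all.
#' @export
choice_series <- function(fly_id, genotype, lit_counts, dark_counts,
                          wavelength_nm = 450, intensity_uw_cm2 = 10,
                          bin_seconds = 60) {
  if (!is_nonneg_int_vector(lit_counts) || !is_nonneg_int_vector(dark_counts))
    stop_field("lit_counts/dark_counts", "must be nonnegative integers")
  if (length(lit_counts) != length(dark_counts))
    stop_field("lit_counts/dark_counts", "must have equal length")
  structure(list(fly_id = as.character(fly_id), genotype = as.character(genotype),
                 lit_counts = as.integer(lit_counts),
                 dark_counts = as.integer(dark_counts),
                 bin_seconds = bin_seconds, wavelength_nm = wavelength_nm,
                 intensity_uw_cm2 = intensity_uw_cm2,
                 inactive = sum(lit_counts) + sum(dark_counts) == 0),
            class = "choice_series")
}

ROI_ZTS <- c(5, 11, 17, 23)
ROI_CHANNELS <- c("TIM", "GFP")

#' Validate an ROI fluorescence table
#'
#' Checks the column contract of an ROI quantification table: one row per
#' neuron with its brain id, channel, mean ROI intensity, the brain's
#' background fluorescence, the Zeitgeber time point, and genotype.
#'
#' @param table a data.frame with columns `brain_id`, `neuron_id`, `channel`,
#'   `mean_intensity`, `background_intensity`, `zt`, `genotype`.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validate_roi_table <- function(table) {
  need <- c("brain_id", "neuron_id", "channel", "mean_intensity",
            "background_intensity", "zt", "genotype")
  missing <- setdiff(need, names(table))
  if (length(missing))
    stop_field("roi table", paste("is missing columns:",
                                  paste(missing, collapse = ", ")))
  if (!all(table$channel %in% ROI_CHANNELS))
    stop_field("channel", "must be one of TIM, GFP")
  if (!all(table$mean_intensity >= 0))
    stop_field("mean_intensity", "must be nonnegative")
  if (!all(table$background_intensity > 0))
    stop_field("background_intensity", "must be positive")
  if (!all(table$zt %in% ROI_ZTS))
    stop_field("zt", "must be one of 5, 11, 17, 23")
  table
}
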