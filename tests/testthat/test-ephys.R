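# Spike detection, firing-frequency ratios, evoked potentials, basal
# metrics, firing-mode classification.

test_that("spike detection finds injected templates and respects refractoriness", {
  # flat noiseless trace: no spikes
  p0 <- genotype_preset("flat", ephys = list(
    rmp_mv = -40, basal_rate_hz = 0, depol_amplitude_mv = 0, noise_sd_mv = 0))
  rec0 <- simulate_voltage(p0, seed = 1)
  expect_equal(sum(lengths(lapply(detect_spikes(rec0), `[[`, "spike_times_s"))), 0)

  # known spike times at preset noise: all found within 1 ms
  proto <- sweep_protocol(n_sweeps = 1)
  p <- genotype_preset("noisy", ephys = list(
    basal_rate_hz = 0, depol_amplitude_mv = 0, noise_sd_mv = 2))
  rec <- simulate_voltage(p, proto, seed = 4)
  fs <- rec$sampling_hz
  truth <- c(5, 20, 40, 60, 80, 100, 120)
  tpl <- crylight:::spike_template(fs, amp_up = 60 - (-37))
  v <- rec$voltage_mv
  for (ts in truth) {
    i <- round(ts * fs) + 1
    v[i:(i + length(tpl) - 1)] <- v[i:(i + length(tpl) - 1)] + tpl
  }
  rec$voltage_mv <- v
  det <- detect_spikes(rec)[[1]]$spike_times_s
  expect_length(det, 7)
  expect_true(all(vapply(truth, function(ts) min(abs(det - ts)) <= 1e-3,
                         logical(1))))

  # two templates 1 ms apart with a 2-ms refractory window: one detection
  v2 <- rep(-40, 150 * fs)
  for (ts in c(10, 10.001)) {
    i <- round(ts * fs) + 1
    v2[i:(i + length(tpl) - 1)] <- v2[i:(i + length(tpl) - 1)] + tpl
  }
  rec2 <- voltage_recording("c", "g", v2, fs, proto)
  expect_length(detect_spikes(rec2)[[1]]$spike_times_s, 1)
})

test_that("spike detection against generator ground truth is near-perfect", {
  p <- genotype_preset("std")   # default preset noise
  rec <- simulate_voltage(p, seed = 11)
  truth <- unlist(attr(rec, "ground_truth")$spike_times)
  det <- unlist(lapply(detect_spikes(rec), `[[`, "spike_times_s"))
  hits <- vapply(truth, function(ts) any(abs(det - ts) <= 2e-3), logical(1))
  false_det <- vapply(det, function(td) !any(abs(truth - td) <= 2e-3), logical(1))
  expect_gte(mean(hits), 0.99)
  expect_lte(mean(false_det), 0.01)
})

test_that("firing-frequency ratio follows its arithmetic contracts", {
  proto <- sweep_protocol()   # 50/5/95 x 5
  # stationary 1-Hz train: every ratio exactly 1
  trains <- make_trains(rep(list(seq(0.5, 149.5, by = 1)), 5))
  ff <- firing_frequency_ratio(trains, proto)
  expect_equal(ff$baseline_rate_hz, 1)
  expect_equal(ff$ff_ratio, 1)
  expect_equal(ff$post_ratios, rep(1, 4))
  expect_equal(ff$baseline_bin_rates_hz, rep(1, 5))

  # 10 spikes per 10-s baseline bin, 10 spikes in the 5-s stimulus: ratio 2
  base <- as.numeric(outer(seq(0.05, 9.95, length.out = 10), 0:4 * 10, "+"))
  stim <- seq(50.1, 54.9, length.out = 10)
  one <- make_trains(list(sort(c(base, stim))))
  proto1 <- sweep_protocol(n_sweeps = 1)
  ff2 <- firing_frequency_ratio(one, proto1)
  expect_equal(ff2$baseline_rate_hz, 1)
  expect_equal(ff2$ff_ratio, 2)

  # zero baseline spikes: undefined, flagged for exclusion
  ff0 <- firing_frequency_ratio(make_trains(list(c(51, 52, 53))), proto1)
  expect_false(ff0$defined)
  expect_true(is.na(ff0$ff_ratio))
})

test_that("mean FF ratio over stationary Poisson cells is 1 within MC error", {
  set.seed(13)
  proto <- sweep_protocol()
  ratios <- replicate(300, {
    trains <- make_trains(lapply(1:5, function(s) sort(runif(rpois(1, 150), 0, 150))))
    firing_frequency_ratio(trains, proto)$ff_ratio
  })
  ratios <- ratios[!is.na(ratios)]
  expect_lt(abs(mean(ratios) - 1), 2.576 * sd(ratios) / sqrt(length(ratios)) + 0.01)
})

test_that("the low-pass stage has unit DC gain and evoked output is baseline-zero", {
  fs <- 2000
  # constant offset passes unchanged through Gaussian + Butterworth
  x <- rep(-37, 10 * fs)
  y <- smooth_lowpass(x, fs)
  expect_equal(y, x, tolerance = 1e-9)
  expect_error(smooth_lowpass(x, fs, butter_cutoff_hz = 1001), "Nyquist")

  # constant trace: identically zero evoked potential
  p0 <- genotype_preset("flat", ephys = list(
    rmp_mv = -40, basal_rate_hz = 0, depol_amplitude_mv = 0, noise_sd_mv = 0))
  ep0 <- evoked_potential(simulate_voltage(p0, seed = 1))
  expect_equal(max(abs(ep0$delta_mv)), 0, tolerance = 1e-9)
})

test_that("sweep averaging recovers plateau amplitudes", {
  # two noiseless sweeps with +10 and +20 mV plateaus average to +15
  fs <- 2000
  proto <- sweep_protocol(n_sweeps = 2)
  mk <- function(a) {
    p <- genotype_preset("g", ephys = list(
      rmp_mv = -40, basal_rate_hz = 0, depol_amplitude_mv = a,
      tau_on_s = 0.05, tau_off_s = 0.05, gain_hz_per_mv = 0, noise_sd_mv = 0))
    attr(simulate_voltage(p, sweep_protocol(n_sweeps = 1), seed = 1),
         "ground_truth")$depolarization_mv
  }
  v <- c(-40 + mk(10), -40 + mk(20))
  rec <- voltage_recording("c", "g", v, fs, proto)
  ep <- evoked_potential(rec)
  mid_stim <- ep$time_s >= 52 & ep$time_s <= 54.5
  expect_equal(mean(ep$delta_mv[mid_stim]), 15, tolerance = 0.02 * 15)

  # full synthetic preset: plateau within 10%, baseline exactly zero
  p <- genotype_preset("std", ephys = list(depol_amplitude_mv = 10, tau_on_s = 1))
  rec2 <- simulate_voltage(p, seed = 3)
  ep2 <- evoked_potential(rec2)
  stim <- ep2$time_s >= 50 & ep2$time_s < 55
  expect_equal(max(ep2$delta_mv[stim]), 10 * (1 - exp(-5)), tolerance = 0.1)
  expect_lt(abs(mean(ep2$delta_mv[ep2$baseline_idx])),
            1e-9 * max(abs(ep2$delta_mv)))
})

test_that("basal metrics recover RMP and firing rate", {
  # noiseless non-spiking trace at -45 mV
  p0 <- genotype_preset("q", ephys = list(
    rmp_mv = -45, basal_rate_hz = 0, depol_amplitude_mv = 0, noise_sd_mv = 0))
  b0 <- basal_metrics(simulate_voltage(p0, seed = 1))
  expect_equal(b0$rmp_mv, -45)
  expect_equal(b0$basal_rate_hz, 0)

  # default preset (rmp -37, noise + spikes): recovered within 1 mV
  rec <- simulate_voltage(genotype_preset("std"), seed = 6)
  b <- basal_metrics(rec)
  expect_lt(abs(b$rmp_mv - (-37)), 1)

  # 100 spikes over 250 s of pre-stimulus time -> 0.4 Hz
  proto <- sweep_protocol()
  trains <- make_trains(rep(list(seq(0.25, 49.75, length.out = 20)), 5))
  p1 <- genotype_preset("q2", ephys = list(
    rmp_mv = -45, basal_rate_hz = 0, depol_amplitude_mv = 0, noise_sd_mv = 0))
  rec1 <- simulate_voltage(p1, proto, seed = 1)
  b1 <- basal_metrics(rec1, spikes = trains)
  expect_equal(b1$basal_rate_hz, 100 / 250)
})

test_that("firing-mode classification separates tonic from burst trains", {
  reg <- make_trains(list(seq(0.5, 49.5, by = 1)))
  expect_equal(classify_firing_mode(reg), "tonic")

  triplets <- sort(as.numeric(outer(c(0, 0.05, 0.1), seq(1, 45, by = 2), "+")))
  expect_equal(classify_firing_mode(make_trains(list(triplets))), "burst")

  expect_equal(classify_firing_mode(make_trains(list(seq(1, 9)))), "unclassified")

  # burst preset produces burst-classified baseline spiking
  pb <- genotype_preset("b", ephys = list(basal_rate_hz = 2, burst = TRUE,
                                          depol_amplitude_mv = 0))
  recb <- simulate_voltage(pb, seed = 9)
  spb <- detect_spikes(recb)
  pre <- lapply(spb, function(tr)
    spike_train(tr$sweep_index, tr$spike_times_s[tr$spike_times_s < 50]))
  expect_equal(classify_firing_mode(pre), "burst")
})
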