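# Synthetic-data generators: determinism, conservation laws, closed-form
# and distributional oracles.

test_that("locomotor generator is seed-deterministic and Poisson-calibrated", {
  p <- genotype_preset("flat", locomotor = list(amplitude = 0, base_rate = 2))
  a <- simulate_locomotor(p, n_flies = 20, days_ld = 1, days_dd = 0, seed = 7)
  b <- simulate_locomotor(p, n_flies = 20, days_ld = 1, days_dd = 0, seed = 7)
  expect_identical(lapply(a, `[[`, "counts"), lapply(b, `[[`, "counts"))

  counts <- unlist(lapply(a, `[[`, "counts"))
  expect_true(all(counts >= 0 & counts == round(counts)))
  # constant-rate Poisson: sample mean within 4 SE of the rate
  se <- sqrt(2 / length(counts))
  expect_lt(abs(mean(counts) - 2), 4 * se)
})

test_that("locomotor generator rejects bad day counts and rhythmic fractions", {
  p <- genotype_preset("g")
  expect_error(simulate_locomotor(p, 2, 0, 0, seed = 1), "at least 1 day")
  expect_error(simulate_locomotor(p, 2, -1, 3, seed = 1), "days_ld")
  expect_error(genotype_preset("g", locomotor = list(rhythmic_fraction = 1.2)),
               "rhythmic_fraction")
})

test_that("arrhythmic tail of a cohort has zero amplitude in ground truth", {
  p <- genotype_preset("g", locomotor = list(rhythmic_fraction = 0.5))
  coh <- simulate_locomotor(p, 10, 1, 1, seed = 3)
  gt <- attr(coh, "ground_truth")
  expect_equal(sum(gt$rhythmic), 5)
  expect_true(all(gt$amplitude[!gt$rhythmic] == 0))
})

test_that("voltage generator honors closed forms and the Poisson baseline", {
  # flat trace: no depolarization, no noise, no spikes
  p0 <- genotype_preset("flat", ephys = list(
    rmp_mv = -45, basal_rate_hz = 0, depol_amplitude_mv = 0, noise_sd_mv = 0))
  rec0 <- simulate_voltage(p0, seed = 1)
  expect_equal(unique(rec0$voltage_mv), -45)

  # noiseless depolarization reaches A(1 - exp(-stim/tau_on))
  p1 <- genotype_preset("depol", ephys = list(
    rmp_mv = -45, basal_rate_hz = 0, depol_amplitude_mv = 10, tau_on_s = 1,
    gain_hz_per_mv = 0, noise_sd_mv = 0))
  rec1 <- simulate_voltage(p1, seed = 1)
  gt1 <- attr(rec1, "ground_truth")
  expect_equal(max(gt1$depolarization_mv), 10 * (1 - exp(-5)), tolerance = 0.01)

  # 1-Hz baseline over 50 s x 5 sweeps: count in Poisson 99% interval of 250
  p2 <- genotype_preset("base", ephys = list(
    basal_rate_hz = 1, depol_amplitude_mv = 0, gain_hz_per_mv = 0))
  rec2 <- simulate_voltage(p2, seed = 42)
  gt2 <- attr(rec2, "ground_truth")
  n_base <- sum(vapply(gt2$spike_times, function(tt) sum(tt < 50), numeric(1)))
  expect_gte(n_base, qpois(0.005, 250))
  expect_lte(n_base, qpois(0.995, 250))

  # determinism
  rec3 <- simulate_voltage(p2, seed = 42)
  expect_identical(rec2$voltage_mv, rec3$voltage_mv)
})

test_that("voltage generator refuses a sampling rate too low for the template", {
  p <- genotype_preset("g")
  expect_error(simulate_voltage(p, sampling_hz = 1000, seed = 1), "sampling")
})

test_that("choice generator conserves counts and matches binomial means", {
  p <- genotype_preset("even")
  coh <- simulate_choice(p, n_flies = 30, minutes = 30, seed = 5)
  for (cs in coh)
    expect_true(all(cs$lit_counts >= 0 & cs$dark_counts >= 0))
  # symmetry at p = 0.5
  mpa <- mean_percent_activity(coh)
  expect_lt(abs(mpa$mean - 50), 3 * mpa$sem)

  # binomial oracle at p = 0.75
  p75 <- genotype_preset("attr", choice = list(
    p_lit = function(m) rep(0.75, length(m)), total_rate = 10))
  coh75 <- simulate_choice(p75, n_flies = 40, minutes = 30, seed = 5)
  m75 <- mean_percent_activity(coh75)
  # binomial SE of the cohort mean: ~300 crossings per fly, 40 flies
  se <- 100 * sqrt(0.75 * 0.25 / (10 * 30)) / sqrt(40)
  expect_lt(abs(m75$mean - 75), 3 * se)

  # zero activity: all-zero series flagged inactive
  pz <- genotype_preset("dead", choice = list(total_rate = 0))
  cz <- simulate_choice(pz, n_flies = 2, minutes = 5, seed = 1)
  expect_true(all(vapply(cz, `[[`, logical(1), "inactive")))
  expect_true(all(unlist(lapply(cz, `[[`, "lit_counts")) == 0))
})

test_that("choice generator rejects out-of-range lit probabilities", {
  p <- genotype_preset("bad", choice = list(p_lit = function(m) rep(1.2, length(m))))
  expect_error(simulate_choice(p, 2, 5, seed = 1), "p_lit")
})

test_that("ROI generator is exact at zero noise and deterministic", {
  p <- genotype_preset("tim", icc = list(noise_cv = 0))
  tab <- simulate_roi(p, n_brains = 3, neurons_per_brain = 4, zt = 23, seed = 9)
  norm <- normalize_roi(tab)
  expect_equal(unique(norm$normalized_intensity),
               p$icc$mean_by_zt[["23"]] / p$icc$background_mean)
  tab2 <- simulate_roi(p, 3, 4, 23, seed = 9)
  expect_identical(tab$mean_intensity, tab2$mean_intensity)
  expect_error(simulate_roi(p, 2, 2, zt = 9, seed = 1), "time point")
})
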