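#' Genotype preset for the synthetic assay generators
#'
#' Bundles the latent parameters the four synthetic generators draw from for
#' one genotype: locomotor rhythm shape, light-evoked membrane response,
#' lit-environment choice probability, and ZT-dependent ROI fluorescence.
#' All numerical values are fixture choices describing plausible assay
#' statistics, not measured biology; the generators return them as ground
#' truth so downstream stages can be tested by parameter recovery.
#'
#' @param name genotype label.
#' @param locomotor list with `tau_h` (free-running period, hours, in
#'   (16, 32)), `base_rate` (mean counts/min), `amplitude` (dimensionless
#'   modulation depth, >= 0), `anticipation_ramp_h` (hours of exponential
#'   ramp before each light transition), `rhythmic_fraction` (in \[0, 1\]).
#' @param ephys list with `rmp_mv` (resting membrane potential),
#'   `basal_rate_hz`, `depol_amplitude_mv` (light-evoked plateau, >= 0),
#'   `tau_on_s`, `tau_off_s` (depolarization kinetics, > 0),
#'   `gain_hz_per_mv` (firing-rate gain on depolarization), `noise_sd_mv`
#'   (Gaussian sample noise), `burst` (flag: cluster spikes in triplets).
#' @param choice list with `p_lit` (function minute -> probability in
#'   \[0, 1\] that a crossing happens on the lit side) and `total_rate`
#'   (mean total crossings/min).
#' @param icc list with `mean_by_zt` (named intensity means for ZT 5, 11,
#'   17, 23), `background_mean` (> 0) and `noise_cv` (>= 0).
#' @return An object of class `genotype_preset`.
#' @export
genotype_preset <- function(name,
                            locomotor = list(),
                            ephys = list(),
                            choice = list(),
                            icc = list()) {
  loc <- utils::modifyList(list(
    tau_h = 24, base_rate = 2, amplitude = 1.5,
    anticipation_ramp_h = 3, rhythmic_fraction = 1), locomotor)
  ep <- utils::modifyList(list(
    rmp_mv = -37, basal_rate_hz = 1, depol_amplitude_mv = 10,
    tau_on_s = 1, tau_off_s = 10, gain_hz_per_mv = 0.2,
    noise_sd_mv = 2, burst = FALSE), ephys)
  ch <- utils::modifyList(list(
    p_lit = function(minute) rep(0.5, length(minute)), total_rate = 10), choice)
  ic <- utils::modifyList(list(
    mean_by_zt = c(`5` = 40, `11` = 45, `17` = 80, `23` = 120),
    background_mean = 40, noise_cv = 0.25), icc)

  check_number(loc$tau_h, "locomotor$tau_h", min = 16, max = 32,
               strict_min = TRUE, strict_max = TRUE)
  check_number(loc$base_rate, "locomotor$base_rate", min = 0)
  check_number(loc$amplitude, "locomotor$amplitude", min = 0)
  check_number(loc$anticipation_ramp_h, "locomotor$anticipation_ramp_h", min = 0)
  check_number(loc$rhythmic_fraction, "locomotor$rhythmic_fraction",
               min = 0, max = 1)
  check_number(ep$basal_rate_hz, "ephys$basal_rate_hz", min = 0)
  check_number(ep$depol_amplitude_mv, "ephys$depol_amplitude_mv", min = 0)
  check_number(ep$tau_on_s, "ephys$tau_on_s", min = 0, strict_min = TRUE)
  check_number(ep$tau_off_s, "ephys$tau_off_s", min = 0, strict_min = TRUE)
  check_number(ep$noise_sd_mv, "ephys$noise_sd_mv", min = 0)
  if (!is.function(ch$p_lit)) stop_field("choice$p_lit", "must be a function")
  check_number(ch$total_rate, "choice$total_rate", min = 0)
  if (!all(names(ic$mean_by_zt) %in% as.character(ROI_ZTS)))
    stop_field("icc$mean_by_zt", "must be keyed by ZT in {5, 11, 17, 23}")
  check_number(ic$background_mean, "icc$background_mean", min = 0, strict_min = TRUE)
  check_number(ic$noise_cv, "icc$noise_cv", min = 0)

  structure(list(name = name, locomotor = loc, ephys = ep,
                 choice = ch, icc = ic),
            class = "genotype_preset")
}

#' Built-in genotype presets
#'
#' Four presets mirroring the experimental design of the assays: a native-CRY
#' positive control (`DmCRY`), two heterologous mosquito CRY1 genotypes
#' (`AeCRY1`, diurnal; `AgCRY1`, nocturnal) and a `cry_null` negative
#' control.  Parameter choices emulate the qualitative contrasts the assays
#' are designed to resolve -- e.g. a longer free-running period and stronger
#' sustained depolarization for `AgCRY1`, no light-evoked response and a
#' low rhythmic fraction for `cry_null`, and a TIM fluorescence profile
#' peaking at ZT23 with its trough at ZT5/ZT11 for all genotypes.  They are
#' fixture choices, not measurements.
#'
#' @return Named list of [genotype_preset()] objects.
#' @export
default_presets <- function() {
  tim_cycle <- c(`5` = 45, `11` = 50, `17` = 85, `23` = 120)
  list(
    DmCRY = genotype_preset(
      "DmCRY",
      locomotor = list(tau_h = 24.0, rhythmic_fraction = 0.9),
      ephys = list(rmp_mv = -37, basal_rate_hz = 1.0, depol_amplitude_mv = 10,
                   tau_off_s = 10, gain_hz_per_mv = 0.25),
      choice = list(p_lit = function(m) rep(0.55, length(m))),
      icc = list(mean_by_zt = tim_cycle)),
    AeCRY1 = genotype_preset(
      "AeCRY1",
      locomotor = list(tau_h = 24.2, rhythmic_fraction = 0.9),
      ephys = list(rmp_mv = -33, basal_rate_hz = 1.5, depol_amplitude_mv = 6,
                   tau_off_s = 5, gain_hz_per_mv = 0.15),
      choice = list(p_lit = function(m) rep(0.65, length(m))),
      icc = list(mean_by_zt = c(`5` = 50, `11` = 55, `17` = 100, `23` = 130))),
    AgCRY1 = genotype_preset(
      "AgCRY1",
      locomotor = list(tau_h = 25.0, rhythmic_fraction = 0.9),
      ephys = list(rmp_mv = -33, basal_rate_hz = 1.5, depol_amplitude_mv = 12,
                   tau_off_s = 20, gain_hz_per_mv = 0.3),
      choice = list(p_lit = function(m) rep(0.35, length(m))),
      icc = list(mean_by_zt = c(`5` = 100, `11` = 105, `17` = 110, `23` = 115))),
    cry_null = genotype_preset(
      "cry_null",
      locomotor = list(tau_h = 23.5, rhythmic_fraction = 0.4),
      ephys = list(rmp_mv = -33, basal_rate_hz = 1.5, depol_amplitude_mv = 0,
                   gain_hz_per_mv = 0),
      choice = list(p_lit = function(m) rep(0.6, length(m))),
      icc = list(mean_by_zt = tim_cycle))
  )
}
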