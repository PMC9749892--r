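---
title: "Assay models and analysis methods in crylight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assay models and analysis methods in crylight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crylight)
```

crylight implements the quantitative workflow behind four assays used to
characterize Cryptochrome-dependent light responses in flies: circadian
locomotor rhythmicity, whole-cell light-evoked electrophysiology,
two-environment light choice, and ROI fluorescence across Zeitgeber time,
plus the two-group statistics layer that compares genotypes.  This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic generators do and do not emulate.

## Locomotor rhythmicity

Activity arrives as per-minute beam-crossing counts from DAM-style
monitors, with ZT0 = lights-on and half-open 1-min bins.  The core statistic
is the chi-square (Sokolove-Bushell) periodogram: for a candidate period of
$P$ bins the series is trimmed to $K = \lfloor N/P \rfloor$ complete cycles
and folded; with column means $M_h$, grand mean $M$ and biased variance
$\hat\sigma^2$ over the retained bins,

$$Q_P = \frac{K \sum_{h=1}^{P} (M_h - M)^2}{\hat\sigma^2},$$

referred to the $\chi^2_{P-1}$ quantile at level $\alpha$.  The incomplete
final cycle is trimmed, not wrapped.

Several quantities around the peak are conventions rather than part of the
statistic, and we fix them as follows:

* **Grid**: 16-32 h in 0.1-h steps (`default_period_grid()`), folded on
  integer bin counts by nearest-bin rounding (6 bins per step at 1-min
  resolution).
* **tau** is the grid period maximizing $Q_P - \chi^2$ threshold among
  supra-threshold periods; **power** is that excess at the peak; **width**
  is the contiguous span of supra-threshold grid periods around the peak.
  These definitions reproduce the magnitudes that FaasX-style toolkits
  print; the exact in-house definitions behind such tools are unpublished,
  so ours are documented interpretations.
* **Significance** means the peak exceeds the $\chi^2$ line at
  $\alpha = 0.05$.  (The alternative literal reading -- a p-value of at
  least 0.05 -- would label noise rhythmic, so it is rejected.)
* A fly is **rhythmic** iff significant AND power $\ge 20$ AND width
  $\ge 2$ h; boundaries pass, matching the printed "$\ge$" criteria
  (`rhythmicity_criteria()`).
* An all-constant series has zero variance; it is classified arrhythmic
  with a `degenerate` flag rather than raising an error.
* Only constant-dark bins enter the periodogram (`dd_only = TRUE`); LD days
  feed eduction and anticipation only.

A known limitation of maximizing $Q_P$ with $K = \lfloor N/P \rfloor$: at
period values where the record holds exactly one more complete cycle (24.0 h
in a 7-day DD record), $Q_P$ gains a whole extra cycle of folding, so true
periods up to ~0.3 h above such a boundary can snap down onto it.  Free-run
periods well away from the boundary (e.g. 23.6, 24.7, 25.4 h) are recovered
to within one grid step.

The **anticipation index** for a transition at time $T$ is the mean activity
in $[T-3\,\mathrm{h}, T)$ over the mean in $[T-6\,\mathrm{h}, T)$, computed
per LD day and then averaged across days (the pooling order is ambiguous in
common usage; per-day-then-average weights days equally).  Both windows end
at, and exclude, the transition bin.  For nonnegative counts the index lies
in $[0, 2]$: 1 is no ramping, 2 means all activity fell in the final 3 h.
Days with an empty 6-h window are excluded; with several entrainment days
available the last `n_days` (default 5) are used, since late entrainment
days are the conventional choice when the exact day range is unstated.  The
LD-to-DD boundary is not a transition (no lights-on occurs) and is never
scored.

## Light-evoked electrophysiology

Recordings follow the 50 s dark / 5 s light / 95 s dark protocol repeated
over five sweeps (`sweep_protocol()`), sampled at $\ge 2$ kHz.

**Spike detection** subtracts a ~25-ms running-median baseline and
thresholds the residual at median $+ 6 \times$ MAD with an absolute floor of
10 mV prominence, keeping at most one event per 2-ms refractory window; the
spike time is the peak sample.  The MAD term adapts to noise; the floor
keeps noiseless traces spike-free.  These parameters are configurable and
are declared approximations -- spike-sorting settings of acquisition-side
software are never published in enough detail to copy.

**Firing-frequency ratio**: baseline spikes are pooled across sweeps into
five 10-s bins over the 50-s dark period; the baseline rate is their mean.
The printed convention divides stimulus spikes by a baseline *rate*, so the
stimulus count is converted to Hz before division -- the only reading under
which a stationary train yields a ratio of exactly 1.  Four 10-s
post-stimulus bins (up to 40 s) are reported as rates over baseline.  Cells
with zero baseline spikes have an undefined ratio and are excluded with a
logged flag; no pseudocount is added.  Spike statistics are pooled across a
cell's sweeps and the cell is the statistical unit.

**Evoked potential**: sweeps are aligned on stimulus onset, averaged
pointwise, baseline-adjusted by the mean of the final 10 s of the dark
period (the most recent pre-pulse signal), then low-pass filtered by a
normalized Gaussian kernel ($\sigma = 50$ ms) followed by a zero-phase
3rd-order Butterworth at 2 Hz.  The settings suppress spike transients while
preserving the tens-of-seconds depolarization envelope; all are arguments.
Numerical choices: edges are constant-padded and the filter operates around
the signal mean so DC gain is exactly 1; after filtering, the baseline
window is re-zeroed so its mean is exactly zero rather than merely small.
A cutoff at or above Nyquist is an error.

**Basal metrics**: RMP is the mode of the 1-mV histogram of spike-blanked
pre-stimulus voltage (the mean of samples in the modal bin, so noiseless
traces are recovered exactly); basal rate is pooled pre-stimulus spikes over
total pre-stimulus time.  Firing mode is **burst** when at least half of the
spikes lie in runs of $\ge 3$ spikes with intra-run intervals $\le 100$ ms
flanked by gaps $\ge 300$ ms, **tonic** otherwise, and **unclassified**
below 10 spikes.

## Light choice

Preference per 1-min bin is the percentage of beam crossings on the lit
side over total crossings.  Zero-activity bins are *undefined*, not 50/50 --
imputing neutrality would drag low-activity flies toward no-preference.
The per-fly mean over defined bins in the first 30 min (window anchored at
ZT0) is the unit entering group statistics; fully inactive flies are
excluded with a flag.  Complementarity (lit% + dark% = 100) and label-swap
symmetry hold exactly by construction.

## ROI fluorescence

Each neuron's mean ROI intensity is divided by its own brain's background
fluorescence.  The ratio convention (not subtraction) is dimensionless and
invariant to per-brain scaling, which is what makes values comparable
across imaging sessions; background is taken as one value per brain.
Per-ZT summaries pool all neurons from all brains (the neuron is the unit),
with a per-brain-first option behind a flag.  Measured time points are ZT 5,
11, 17 and 23.

## Two-group statistics

`compare_two_groups()` dispatches on an Anderson-Darling normality test
(case-3 critical values, estimated mean and variance, via the `nortest`
implementation) at $\alpha = 0.05$: if both samples pass, an F-test selects
a pooled ($p \ge 0.05$) or Welch one-tailed t-test; otherwise Mann-Whitney
U, exact when both $n \le 8$ without ties and tie-corrected normal
approximation otherwise.  The Anderson-Darling test requires $n \ge 8$, so
smaller samples go to the rank branch.  Tail directions must be declared per
contrast; inferring them from the data would double the type-I error, so
that is refused.  A nominal level written as 0.5 in common protocol text is
treated as the evident typo for 0.05.

Families of raw p-values (one figure-panel analysis per family, the key is
configurable) are adjusted by Benjamini-Hochberg step-up and thresholded at
$q = 0.1$.  Significance is labeled on two tiers, both inclusive: black
from raw p at 0.05 / 0.005 / 0.001 and red from FDR-adjusted p at 0.1 /
0.05 / 0.01.

## Synthetic generators

Because no raw recordings are distributed with the assays, every stage is
validated against seed-reproducible generators that return their latent
parameters (`ground_truth` attributes and JSON sidecars), making each
analysis a parameter-recovery exercise.  The generator shapes are fixture
choices, not biological claims:

* **Locomotor**: inhomogeneous Poisson counts with rate
  $r(t) = \text{base} \cdot (1 + \text{amplitude} \cdot s(\phi))$, where
  $s$ has raised-cosine morning/evening lobes (half-width 4 h, giving
  several-hour activity bouts and periodogram widths in the 2-5 h range
  that real cohorts show) plus exponential ramps rising over the
  anticipation window before each transition.  In DD the phase free-runs
  at `tau_h` with no LD masking -- the simplest model that exercises the
  periodogram.  A `1 - rhythmic_fraction` tail of each cohort has
  amplitude 0.
* **Voltage**: rmp + light-evoked depolarization
  ($A(1-e^{-t/\tau_{on}})$ during light, exponential $\tau_{off}$ decay
  after) + Gaussian noise + spikes from an inhomogeneous Poisson process
  with rate basal $+$ gain $\cdot D(t)$, rendered as a fixed biphasic 2-ms
  template peaking near +60 mV -- large enough that threshold detection is
  unambiguous at preset noise.  Burst presets draw Poisson onsets at a
  third of the rate and emit 50-ms-ISI triplets.
* **Choice**: total crossings Poisson per minute, lit share Binomial with
  the preset's (possibly time-varying) probability; conservation
  lit + dark = total holds per bin by construction.
* **ROI**: lognormal multiplicative noise with exact means and the given
  CV around per-ZT intensity means and a per-brain background; the TIM
  presets peak at ZT23 with the trough at ZT5/ZT11.

All randomness flows from one explicit seed per call and the caller's RNG
state is left untouched.  What the generators do **not** emulate: masking
and startle responses to light transitions, inter-fly parameter
heterogeneity beyond the rhythmic/arrhythmic split, bursty locomotor bout
structure (counts are conditionally independent across bins),
conductance-based spike waveform diversity, electrode drift, or optical
bleaching.  Tests passing on these fixtures therefore certify the analysis
arithmetic and its contracts, not robustness to every artifact of real
recordings.

## Built-in presets and the demo run

`default_presets()` ships four genotypes (DmCRY, AeCRY1, AgCRY1, cry_null)
whose parameters encode the qualitative contrasts the assays are designed
to resolve: a longer free-running period and stronger sustained
depolarization for AgCRY1, no light response and a low rhythmic fraction
for cry_null, RMP near -37 mV for DmCRY, attraction vs. avoidance choice
probabilities, and TIM cycling with a ZT23 peak.  The numbers are fixture
choices.  `run_pipeline()` over `inst/extdata/demo_config.yaml` runs all
four assays at demo scale -- 8 flies x 9 days locomotor, 2 cells x 5 sweeps
ephys, 20 flies x 30 min choice, 3 brains x 4 neurons x 4 ZT points ICC per
genotype -- chosen so a full run takes well under a minute while every
stage still has enough data to estimate its quantities; the analysis
scripts under `analysis/` use similar sizes.  Determinism is end-to-end:
identical config and seed give byte-identical output files, and the
manifest records the package version, seed and a hash of the scientific
configuration.
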