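---
title: "Methods: windowed quality metrics, channel pruning and the threshold sweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed quality metrics, channel pruning and the threshold sweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsprune)
```

## Background

Channel pruning decides, per source–detector pair, whether a recording
segment carries usable physiological signal. For infant fNIRS the
decision is harder than for adults: coupling through fine hair and
small heads is unstable, infants move constantly, and the infant
cardiac rhythm (roughly 1.3–3.2 Hz at rest) is faster and less cleanly
sampled than the adult one. `nirsprune` implements two pruning
families — the coefficient-of-variation (CV) wavelength-difference rule
and the windowed scalp-coupling-index / peak-spectral-power (SCI/PSP)
rule — plus the apparatus needed to compare them fairly: motion-aware
windowing, a retention-matched threshold sweep, and a bootstrap
mixed-model stage.

## Quality metrics

All signal-level moments use the **population** standard deviation
(denominator $n$); the statistics stage uses the sample convention for
variable scaling, mirroring the usual regression practice. The two
conventions are pinned by tests.

* $CV = \sigma / |\mu|$ on raw intensity. Scale-invariant; infinite
  for a zero-mean signal.
* $\mathrm{SNR} = 20 \log_{10}(\mu/\sigma)$ in dB, defined for
  positive-mean intensity signals. A channel's SNR is the mean of its
  two wavelengths' SNRs over the concatenated motion-free windows; TRC
  SNR averages this over the retained task-relevant channels.
* **Cardiac band-pass**: zero-phase (forward–backward) order-3
  Butterworth on 1.3–3.2 Hz. The contract is behavioural, not
  nominal: passband centre attenuation below 1 dB, an octave outside
  either edge above 20 dB. Zero-phase filtering matters because SCI is
  a zero-lag statistic.
* **SCI**: Pearson correlation of the two wavelengths'
  band-pass-filtered window signals, i.e. the zero-lag value of the
  cross-correlation of the unit-variance signals.
* **PSP**: the windows' unit-variance signals are cross-correlated at
  all lags with the unbiased estimator
  $c_k = \frac{1}{N-|k|}\sum_n \bar x_{\lambda 1}[n]\,
  \bar x_{\lambda 2}[n+k]$, and PSP is the maximum of the one-sided
  normalized power spectrum $2\,|\mathrm{DFT}(c)|^2 / M^2$
  ($M = 2N-1$), DC excluded. The discrete formula *is* the contract: a
  brute-force lag-domain/DFT oracle reproduces it to $10^{-9}$ in the
  tests. With the default 3-s window at 10 Hz, a perfectly coherent
  pure sinusoid pair scores ≈ 0.24 and independent white noise ≈ 0.02,
  so the conventional threshold grid (0.005–0.1) spans the informative
  range. The peak search is not restricted to the cardiac band: the
  signals are already band-limited, so the maximum falls in band
  anyway, and an unrestricted maximum keeps the definition
  self-contained.

### Windows and degenerate data

The recording is partitioned into non-overlapping 3-s windows from the
first sample; a trailing partial window is discarded. The convention is
half-open: a sample on a boundary belongs to the later window. A window
with zero variance after filtering (flat-lined or saturated data) has
no defined SCI/PSP and **counts as failing** rather than missing — flat
data is bad data. A per-window threshold of zero (or below) disables
that conjunct of the quality test; this is exactly how the SCI-only
variant is constructed (`psp_threshold = 0`) and makes the `(0, 0)`
configuration vacuous for non-degenerate windows, which a strict
comparison against an SCI that may be negative would not be.

## Motion detection

The detector works on optical-density changes
$\Delta OD(t) = -\ln(I(t)/\bar I)$, not raw intensity — the convention
of the amplitude/deviation detectors this one reproduces; the
conversion is isolated in `optical_density()` so it can be toggled. A
sample is flagged when *any* `tMotion` = 1-s window covering it has
range exceeding `amp_thresh` = 0.4 **or** `stdev_thresh` = 15 × the
whole-series population SD of `diff(ΔOD)`; equivalently, range above
the smaller of the two cuts. Flags are dilated ± `tMask` = 1 s,
truncated at the recording edges, and a flag on either wavelength flags
the channel. Anchoring the deviation criterion on the whole-series
first-difference SD means the criterion adapts to each channel's noise
floor; on nearly noiseless synthetic signals it becomes arbitrarily
strict, so tests that exercise the amplitude criterion alone include a
realistic noise floor. Note the per-sample window-coverage definition
smears a detection over the detection window length as well as the mask:
a 0.5-s excursion yields roughly $0.5 + 2(t_{Motion}-\delta) +
2\,t_{Mask} \approx 4.3$ s of flagged samples, verified sample-exactly
against a brute-force oracle.

## Pruning rules

* **CSE**: minimum raw intensity below `3e-4` anywhere → excluded
  before all other analysis; independent of motion masks; idempotent.
* **CV rule**: CVs per wavelength on the concatenation of clean-window
  samples (not per-window averages — the closest reading of "computed
  on motion-free data"); prune when the difference *strictly exceeds*
  0.2. The strict/inclusive boundary is genuinely ambiguous in common
  usage, so it is a flag (`cv_config(strict =)`) with the strict form
  as default and a test pinning the boundary.
* **SCI/PSP rule**: retained iff
  `good_fraction ≥ q_threshold` (default 0.75) over clean windows.
* Channels with **zero clean windows** are excluded (counted as not
  retained): a channel with no evaluable data cannot be certified.

## The sweep and retention matching

Per participant, masks, clean windows, per-window SCI/PSP and
per-channel SNR are computed once; each of the 18 × 20 grid points then
only re-counts windows, which makes the full sweep linear in recording
length rather than in grid size. Matching against CV pruning ranks grid
points by $|\overline{CR} - \overline{CR}_{CV}|$ and by the absolute
difference in excluded-participant counts (exclusion: fewer than 60 %
of acceptable channels retained — a descriptive convention exposed as
`exclusion_frac`), with average ranks for ties; the combined rank sum
is minimized, and residual ties resolve toward lower thresholds, i.e.
the least aggressive matching configuration. Rank-sum is one of several
defensible aggregations; it is the documented contract here.

The quality/retention trade-off tool fits a **monotone non-increasing
least-squares line** of grid-mean TRC SNR on grid-mean CR (slope
clipped at zero) and recommends the grid point with the largest
positive residual. A pointwise monotone (isotonic) fit was considered
and rejected: it interpolates any already-monotone cloud exactly,
making every residual zero and the recommendation vacuous; the
constrained line keeps the monotonicity semantics while leaving
"above the trend at comparable retention" detectable. On an exactly
collinear cloud the recommendation degenerates to the
retention-preferring choice (highest CR, then lowest thresholds).

## Statistical stage

Variables are scaled and centered as $x' = (x - \bar x)/s_x$ with the
sample SD; constant vectors scale to zeros with a degeneracy flag. The
method comparison fits `outcome ~ method + (1|ID)` and reports the
three pairwise contrasts with Wald normal p-values multiplied by the
family size (default 3, per analysis cell — the family could
defensibly span all cells, which would simply multiply by a larger
`m`) and capped at 1. These p-values are diagnostics; when residuals
are non-normal the bootstrap is the primary inference path.

The full model uses the threshold values, age, PoM, task, cohort and
CSE count with the interaction set given in the README, participant
random intercepts, and threshold-by-cohort random intercepts grouped on
the discrete threshold levels crossed with cohort. **Age** enters as a
scaled numeric by default — age is ordered and the reporting convention
of a single coefficient per interaction implies a numeric coding — with
`age_numeric = FALSE` switching to a five-level factor. Constant terms
(single-cohort cells, all-zero CSE) are dropped from the formula
automatically rather than producing rank-deficient fits.

The bootstrap resamples **rows** with replacement (fixed seed), refits,
and reports the mean, 2.5/97.5 percentiles and SD of each fixed
effect; resamples that fail to fit are dropped and counted. A known
limitation, stated rather than hidden: row resampling treats rows as
exchangeable, so for covariates that are constant within participant
(like PoM) it understates cluster-level uncertainty and the intervals
run anti-conservative. The parameter-recovery tests therefore use a
generator (`simulate_analysis_rows()`) with a moderate
participant-intercept SD, and fit the unscaled outcome, on whose scale
the injected coefficients are defined.

## The synthetic cohort generator

The generator is the package's substitute for restricted infant data;
it emulates the *statistical structure* the pipeline assumes, not
optode-level physics. Per channel with coupling quality $c \in [0,1]$:

$$I_\lambda(t) = B_\lambda\,\bigl(1 + a(c)\,s_\lambda(t) + d(t) + r(t)
  + w_\lambda(t) + \epsilon_\lambda(t)\bigr)\, e^{-A(t)}$$

* **Cardiac**: $s_1$ is a sinusoid plus a 0.2-amplitude second
  harmonic (harmonic content keeps PSP testing non-trivial) at a
  frequency drawn from 1.5–2.4 Hz — within the nominal infant band
  while keeping the harmonic below Nyquist at 10 Hz;
  $s_2 = c\,s_1 + (1-c)\,h$ with $h$ independent in-band noise, so the
  cross-wavelength coherence — hence SCI — is controlled by $c$.
  $a(c) = a_0(0.2 + 0.8c)$, $a_0$ = 2 % of baseline.
* **Noise**: white, $\sigma = 0.004\,(1 + 6(1-c))$ of baseline — poor
  contact raises the broadband noise floor, which is what ties low
  coupling to low intensity-SNR the way real decoupled optodes behave.
* **Wander**: slow (0.01–0.05 Hz) baseline wander with severity
  $\propto (1-c)^{1.5}$ set once per channel (decoupling affects the
  optode pair as a whole) and mildly perturbed per wavelength. It is
  out of the cardiac band, so it degrades CV and SNR without moving
  SCI/PSP — the blind spot of windowed cardiac metrics.
* **Wavelength imbalance**: with probability 0.1 a channel carries a
  slow instrumental drift on one wavelength only (LED/detector gain
  wander, ambient leakage). These channels trip the CV-difference rule
  while their cardiac coherence is intact.
* **Motion**: array-wide spike (0.2–0.8 s, raised-sine) and step
  events in $\Delta OD$ units with per-channel polarity and amplitude
  jitter; steps persist to the end of the recording at a quarter of
  the drawn amplitude (persistent optode shifts are far smaller than
  transient excursions). The scheduled count is
  `round(rate · duration/60)` — deterministic, so a rate can place an
  exact event count, with random placement.
* **Dead channels** (probability 0.05) have baselines scaled by
  $10^{-4}$, far below the signal-extrema cutoff. **Evoked responses**
  follow a 10 s-on/20 s-off block design convolved with a gamma-family
  response, added with opposite polarity across wavelengths in the
  task-relevant channels.

Cohort generation shifts the *location* of the channel-coupling
distribution per participant — preserving its shape, so a bimodal
good/poor mixture stays bimodal — by injected age, cohort, task and
motion effects, and modulates per-participant motion rates on the log
scale. Per-participant RNG streams are derived arithmetically from the
master seed and participant index, so subsets reproduce exactly.

What the generator does **not** emulate: optode geometry and
channel-distance effects, anatomical or hemodynamic forward models,
realistic artifact waveform zoos, hair/pigmentation covariates, or
serial dependence of motion. Passing tests therefore demonstrate the
pipeline's internal correctness and the direction of method contrasts
under the modelled mechanisms — not performance claims about any real
dataset. The motion-artifact taxonomy (spikes and steps only) is a
modelling choice; the literature gives no distributional detail for
infant artifacts.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of 4–9
participants with 60–120 s recordings, the full 18 × 20 grid, 20
replicate cohorts for the directional method comparison, 20 replicates
for effect-sign recovery, and 100–200 bootstrap resamples — sizes
chosen to exercise every code path and give stable Monte-Carlo margins
at desk scale. Other pinned choices: recordings serialize to a
structured JSON text format carrying the standard measurement-list
layout (wavelengths, sampling rate, per-channel-per-wavelength series)
with full double precision; tie-breaks and boundary conventions are as
described above; filters are applied to whole recordings before
windowing so window edges share the same transient treatment.

## Known limitations

Bootstrap intervals are anti-conservative for cluster-constant
covariates (above). CV-vs-QT contrasts on synthetic cohorts are
sensitive to the assumed mix of symmetric wander versus
wavelength-specific imbalance, which real datasets would pin down.
The PSP definition is this package's oracle-pinned contract; other
implementations normalize the cross-correlation spectrum differently,
so absolute PSP values (and thus thresholds) are not interchangeable
across tools without calibration.
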