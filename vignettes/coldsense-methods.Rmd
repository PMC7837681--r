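---
title: "Methods: models, parameters and design choices in coldsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in coldsense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coldsense)
```

coldsense implements the bespoke computations behind a cold-exposure
feeding study in mice: fiber-photometry recordings of hypothalamic AgRP
neurons during temperature ramps, indirect-calorimetry energy-balance
phenotyping, and Fos/reporter colocalization counting. Every pipeline is
paired with a synthetic-data generator carrying full ground truth, so the
whole analysis chain can be exercised and validated without animal data.
This vignette explains the models, the parameters that matter, and the
design decisions taken where the methods left choices open.

## Frequency-multiplexed photometry and lock-in demodulation

Two excitation LEDs interrogate the same GCaMP6s population: 470 nm
(calcium-dependent) and 405 nm (the isosbestic point, calcium-independent,
reporting bleaching and motion only). Both are sinusoidally
amplitude-modulated at carriers chosen to be non-divisible — 331 Hz for
470 nm and 231 Hz for 405 nm — and a single photodetector samples the sum
at 1017.25 Hz. The acquisition model in the generator is

$$v(t) = A_{470}(t)\,\sin(2\pi\,331\,t) + A_{405}(t)\,\sin(2\pi\,231\,t) + \varepsilon(t),$$

with the channel envelopes $A_c(t)$ varying slowly relative to the
carriers.

`lockin_demodulate()` inverts this by quadrature demodulation: the samples
are multiplied by $\sin$ and $\cos$ references at the channel's carrier,
low-passed, and the envelope taken as $2\sqrt{I^2+Q^2}$. Using the
quadrature magnitude removes any dependence on the (unknown) phase of the
acquisition clock. Numerical choices:

* **Low-pass filter.** Zero-phase filtering with a squared 4th-order
  Butterworth magnitude response, applied in the frequency domain. The
  default cutoff of 20 Hz sits far below the 100 Hz carrier separation
  (isolation) and far above GCaMP6s bandwidth (fidelity). The nearest
  demodulation artifacts — the difference tone at 100 Hz and the aliased
  double-frequency terms — are attenuated by more than five orders of
  magnitude.
* **Edges.** The first and last $2/f_c$ seconds sit in the filter settling
  region; they are flagged in the envelope's `edge` field, never deleted.
  Downstream means exclude flagged samples by default.
* **Decimation.** Output is decimated by 10 (to ~101.7 Hz), which
  preserves transients with decay constants around a second while
  shrinking downstream arrays tenfold.
* **Cross-talk.** `crosstalk_report()` quantifies channel leakage either
  from single-channel calibration segments ("measured") or from synthetic
  single-carrier tones through the same filter chain ("simulated"). No
  claim of equivalence to any vendor's real-time demodulator output is
  made.

## The dF/F pipeline

The correction chain for a temperature-ramp session is:

1. **Bleach removal.** A double exponential
   $b(t) = a_1 e^{-t/\tau_1} + a_2 e^{-t/\tau_2} + c$ is fit to each
   channel's raw trace by nonlinear least squares and subtracted.
   Food-presentation sessions, which are short, use a linear baseline
   instead. The fit uses the raw Levenberg–Marquardt optimizer with a
   multi-start schedule over the $\tau$ grid \{10, 60, 300, 1000\} s
   (all pairs), bounds $\tau \in [1, 10^4]$ s and non-negative
   amplitudes, keeping the restart with the lowest residual sum of
   squares; time constants are reported in the convention
   $\tau_1 \le \tau_2$. If no start converges, a
   single-exponential-plus-constant fallback is fitted and a
   `fit_failure` flag raised. A constant trace is handled exactly
   ($a_1 = a_2 = 0$). Traces longer than 20,000 samples are thinned for
   parameter estimation only; the fitted baseline and RSS are evaluated on
   the full series.
2. **Motion correction.** The detrended 405 trace is regressed onto the
   detrended 470 trace by ordinary least squares, and
   `corrected470 = detrended470 − gain·detrended405 − offset`. The OLS
   scale-and-offset generalizes plain subtraction to unequal channel
   gains; a `unit` mode forces gain 1. A zero-variance 405 channel sets
   the gain to 0 with a `degenerate_405` flag rather than failing.
3. **dF/F.** `100 · corrected470 / median(raw470)` — the session median of
   the *raw* 470 channel is the denominator, because the corrected trace
   is centred near zero and its own median would be unusable. dF/F is
   consequently invariant to overall intensity rescaling.

**Order of corrections.** Descriptions of this class of pipeline are
ambiguous about whether the isosbestic subtraction happens before or after
baseline fitting. We detrend both channels first and then regress,
because subtracting un-detrended channels conflates bleaching (different
amplitude in each channel) with motion (shared up to a gain). A strict
subtraction-first mode (`order = "subtract_first"`) is provided for
comparison.

**Epoch quantification.** `epoch_means()` averages dF/F within each
constant-temperature hold over the half-open window `[start, end)`,
excludes the 60-s ramp transitions entirely, averages hold-epoch means
(not pooled samples) per temperature, and reports
`delta_14_minus_30 = mean(14 °C holds) − mean(30 °C holds)`. Tests verify
bit-identical output when ramp samples are corrupted.

**Default session protocol.** A 5-min baseline hold at the initial 22 °C,
a 60-s ramp to a 10-min hold at 30 °C (thermoneutrality), then two
repeats of \{60-s ramp, 10-min 14 °C hold, 60-s ramp, 10-min 30 °C
hold\}. The lead hold matters beyond protocol fidelity: it places the
steep early photobleach outside the quantified epochs, anchoring the
baseline fit. Without it, the least-squares fit trades the genuine
~300-s bleach component for a slow tilt that partially absorbs the
14/30 alternation, biasing small effects by more than 10%; with it the
recovery bias is a few percent (measured in the acceptance suite at
effects of 1, 3 and 5 percentage points over 20 seeds each).

**Food-response QC.** A working preparation suppresses AgRP activity
rapidly when chow is presented to a fasted animal. `food_response_qc()`
computes `drop = mean dF/F over [event, event+300 s) − mean over
[event−120 s, event)` and passes the session iff `drop ≤ −10` percentage
points (boundary inclusive). The 120/300-s windows are configuration
defaults reported with every result; the method description gives no
values. Sessions failing the rule model surgical misses and are excluded.

## The synthetic photometry generator

The 470 envelope is `bleach(t) + F0·(signal + gain·motion + noise)` with
`F0` the plateau intensity; the 405 envelope shares the bleach family and
the motion trace (different gain) but carries no calcium signal.

* **Transients:** an inhomogeneous Poisson process (thinning algorithm)
  convolved with a peak-normalized difference-of-exponentials kernel,
  rise 0.2 s and decay 1.5 s — GCaMP6s-order kinetics. Baseline rate
  0.1 Hz and mean amplitude 2% dF/F are placeholders: no published value
  pins transient statistics for this population under cold, and both are
  exposed in the configuration.
* **Cold effect:** cold exposure raises the transient rate (default
  2× at 14 °C) and adds a tonic envelope offset. The tonic term is set so
  that the *total* expected 14-minus-30 epoch-mean difference equals
  `effect_size` exactly, accounting for the extra transient mass
  (rate × amplitude × kernel integral). This makes round-trip recovery
  well defined; detrending with the true baseline recovers the injected
  effect to three decimals.
* **Motion:** a band-limited (0.5–5 Hz Butterworth-filtered) Gaussian
  process added to both channels with gains 1.0 / 0.9, reflecting the
  assumption behind isosbestic correction that the artifact is shared.
* **Bleach:** per-channel double exponentials; defaults
  (5, 30 s, 2, 300 s, plateau 100) put most drift in the first several
  minutes, as these recordings show. `bleach_t0` shifts the decay to
  model pre-recording tether time.
* **Food sessions:** linear drift plus an exponential-onset suppression
  (τ = 30 s) after the event. The responder default is a 30-point drop:
  fasted-refeed positive controls suppress far more than the 10-point
  exclusion floor, and the session-wide linear detrend absorbs roughly a
  third of a mid-session step, so responders and misses remain cleanly
  separable — the QC accuracy property is a test of the classifier, not
  of a marginal effect.

What the generator does **not** emulate: hemodynamic contamination,
sensor nonlinearity, wavelength-dependent motion artifacts, slow plateau
drift from fluid accumulation, or real transient waveform diversity.
Passing round-trip tests therefore demonstrates internal consistency of
the pipeline under its own assumptions, not performance on real tissue.

## Indirect calorimetry

Heat production uses the abbreviated Weir equation with the
urinary-nitrogen term omitted:

$$\mathrm{EE}\ (\text{kcal/hr}) = 60\,(3.941\,\dot VO_2 + 1.106\,\dot VCO_2),\qquad \dot V\ \text{in L/min}.$$

The coefficients are a module constant (`weir_coefficients()`),
configurable. RQ is $\dot VCO_2/\dot VO_2$, flagged outside [0.6, 1.1].
The generator *inverts* the same relation (given target EE and RQ,
$\dot VO_2 = \mathrm{EE}/(60(k_1 + k_2\,\mathrm{RQ}))$), which guarantees
the forward computation recovers EE and RQ exactly at zero noise — a
deliberate round-trip identity, tested as such.

* **Intake** is the non-negative hopper-mass decrement per interval times
  the diet's metabolizable energy density (default 3.36 kcal/g, a
  configuration constant for a standard 5001 chow, not a measured value).
  Positive jumps — refills, weighing artifacts — are zeroed and flagged,
  making cumulative intake monotone. The generator starts feeding after
  the first row because the interval table carries no t = 0 reference
  mass, keeping conservation exact: summed intake equals total decrement
  × density, bit for bit.
* **Photoperiod reduction** assigns each interval to light or dark by its
  midpoint — unambiguous for intervals straddling a transition — and
  supports schedules wrapping midnight (12:12 and 14:10 both tested).
* **Cold-onset latency** (`detect_onset()`): first interval exceeding
  baseline mean + k·SD (k = 3) with a persistence requirement of 2
  consecutive intervals to reject single-interval spikes; latency is the
  1-based interval index times the interval, so resolution equals the
  sampling interval (5 min in acute mode). With a zero-variance baseline
  the threshold falls back to an absolute rise. Because a step lands
  mid-interval, the earliest measurable onset is the first interval whose
  midpoint follows it; the validation criterion scores detection at that
  interval or the next. Baseline windows of ~2 h (24 intervals at 5 min)
  estimate the threshold stably; 1-h windows are noticeably noisier.

Default generator conditions: EE baseline 0.45 kcal/hr with a 0.12
kcal/hr cold step (mouse scale), RQ 0.85, EE noise SD 0.02 kcal/hr,
feeding bouts of 0.25 g at 1.0 / 0.65 / 0.4 bouts/hr at 14 / 22 / 30 °C
(non-increasing in ambient temperature), Poisson beam breaks doubled in
the dark phase.

## Fos / reporter colocalization

`threshold_count()` re-implements threshold-and-count particle analysis:
a global intensity threshold (strictly greater), 8-connected components,
and an inclusive pixel-area filter. The labeling is an iterative
label-propagation pass vectorized over the 8 neighbor shifts — chosen
over the available library routine, which is 4-connected. The manual
"threshold adjusted to minimize background" step has no closed form; the
optional `auto_threshold()` surrogate uses mean + 2 SD of the background
(pixels at or below the 90th percentile) and is always logged.

`colocalize()` marks a green (reporter) object colocalized when the
centroid of some red (Fos) object falls inside its mask; each red object
matches at most one green, and a green containing several red centroids
counts once. An area-overlap mode (red overlap ≥ 50%, ties broken by
nearest green centroid) is provided since overlap rules in this
literature are rarely stated. `section_series_summary()` sums counts
across the (default eight) rostro-caudal sections and computes the
overall percent from summed counts, not averaged percents.

The blob-field generator renders Gaussian blobs (σ = radius/2) with a
controlled colocalized subset and enforces pairwise centre separation of
2× the blob radius when non-overlap is requested, erroring when the
requested density is infeasible. It does not emulate uneven illumination,
nuclear/cytoplasmic structure, or anisotropic point-spread functions.

## Inferential contrasts

* `paired_t()`: $t = \bar d/(s_d/\sqrt n)$, two-tailed, df = n − 1;
  zero-variance differences are an explicit error. The test suite
  cross-checks against `stats::t.test` and verifies the empirical type-I
  rate at n = 8 over 10,000 null replicates.
* `holm_sidak()`: step-down Holm–Šidák,
  $\tilde p_{(i)} = \max_{j\le i}\,[1-(1-p_{(j)})^{m-j+1}]$, clipped to 1,
  returned in input order. Written here because the base adjustment
  routines provide Holm–Bonferroni but not the Šidák variant.
* `perm_interaction()`: the mixed treatment-by-time factorial ANOVA used
  for repeated-measures series is replaced by an assumption-light
  permutation surrogate — subject profiles are centred on their own means
  (removing the random intercept), the statistic is the sum over
  timepoints of squared between-treatment mean differences, and treatment
  labels are permuted across subjects with
  $p = (1 + \#\{T^{perm} \ge T^{obs}\})/(1 + n_{perm})$. No
  coefficient-level replication of commercial mixed-model output is
  attempted; reports label every contrast with the method actually
  applied.

## Sessions, files and reproducibility

Session objects round-trip through a CSV + JSON-sidecar dialect
(`write_session()` / `read_session()`): plain CSV with fixed,
unit-bearing column names (`vo2_ml_min`, `hopper_g`, ...) and a sidecar
carrying the schema version, payload type, rates, schedules, events and
free-form metadata. Invariants are re-validated on both write and read;
non-monotone timestamps, unknown schema versions and corrupt files give
structured errors naming the problem. Times are seconds from session
start; intervals are half-open `[start, end)`. Every CLI run logs its
configuration hash, seed and package version. An HDF5 dialect was left
out; the format layer is isolated so one can be added without touching
the analysis code.

## Problem sizes used in the validation suite

The packaged tests run the full chain at the study's own scales:
20-minute raw recordings at 1017.25 Hz for demodulation fidelity
(10 seeds), 60-minute envelope-level ramp sessions for effect recovery
(20 seeds per effect size), 100 food-presentation sessions for QC
accuracy, 24-hour acute calorimetry tables, 50 noisy 256×256 fields for
counting, and 10,000 null replicates for t-test calibration. These sizes
were chosen so each property is estimated with comfortable margin while
the whole suite stays desk-scale.

## Known limitations

* The demodulator is an offline re-implementation; equivalence to any
  specific real-time processor's output is not claimed.
* The double-exponential baseline fit can absorb part of a slowly
  alternating signal when the session lacks a signal-free anchor period;
  the default protocol's lead hold mitigates but does not eliminate this
  (residual attenuation of a few percent of the injected effect).
* The intake clipping rule is a stand-in for proprietary acquisition
  debouncing; refill handling beyond zero-and-flag is out of scope.
* Atlas registration and anatomical segmentation are out of scope for the
  imaging module: it counts whatever field it is given.
* The permutation interaction test is exchangeable-under-null across
  subjects; it does not model heteroscedastic time effects.
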