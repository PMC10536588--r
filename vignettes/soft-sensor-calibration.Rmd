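---
title: "Soft-sensor calibration for sourdough fermentation: models, conventions, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soft-sensor calibration for sourdough fermentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermsense)
```

`fermsense` calibrates pulsed gas-sensor-array (GSA) signals against offline
pH and total titratable acidity (TTA) measurements so that both process
variables can be predicted online during sourdough fermentation. This
vignette is the package's own account of the science: the simulated process
and sensor model, the three calibration methods and their numerical
conventions, the evaluation and validation protocol, and what the synthetic
study does and does not establish about real fermenter data.

## The measurement process being modelled

A stirred fermenter holds a flour–water dough (dough yield
`DY = (m_flour + m_water) · 100 / m_flour`; the default 500 g + 500 g gives
DY 200, a pourable dough suited to an impeller). Every 5 minutes a diaphragm
pump pushes headspace gas past a chamber holding three metal-oxide sensors
(TGS822, TGS813, MQ3) for a few seconds; the chamber is then flushed with
oxygen to regenerate the sensors. Each cycle therefore produces one
peak-shaped signal per channel. Offline, pH and TTA are measured at the start
and every hour.

## The synthetic fermentation generator

Real raw traces of this kind are rarely published, so the package ships a
first-class, tested generator ([sim_config()], [simulate_run()]) whose
defaults define the study conditions used throughout the test suite.

**Kinetics.** pH follows a falling logistic,

$$pH(t) = pH_\infty + \frac{pH_0 - pH_\infty}{1 + e^{\,r\,(f t - t_{1/2})}},$$

and TTA rises linearly, $TTA(t) = TTA_0 + s\, f\, t$. Temperature enters both
through a single Q10 time-warp $f = q_{10}^{(T-30)/10}$ referenced to 30 °C;
warming from 28 °C to 32 °C therefore strictly shortens the time to the
half-way pH drop, matching the observed "faster process when warmer"
behaviour. Defaults ($pH_0 = 5.8$, $pH_\infty = 3.6$, $r = 0.9\,h^{-1}$,
$t_{1/2} = 5$ h, $TTA_0 = 6$, $s = 0.7$ mL/(10 g·h), $q_{10} = 2$) describe a
typical 10 h rice/wheat sourdough at DY 200; they were chosen once as
plausible mid-range values and are not tuned further. `table2_design()`
varies $pH_0$, $TTA_0$ and the slope per flour label to mimic wholegrain
(higher initial pH and TTA) versus white flours.

**Latent activity.** The emission driving the sensors is the normalized
acidification extent $a(t) = (pH_0 - pH(t))/(pH_0 - pH_\infty) \in (0,1)$, a
monotone sigmoid: the volatile load of the headspace (CO₂, ethanol, volatile
acids) accumulates as fermentation progresses. An alternative — defining
activity as the TTA production *rate* — degenerates to a constant under the
linear TTA law and would leave the sensor features without any information
about the process state, so the extent form was adopted.

**Sensor response.** Within a cycle starting at $t_k$, channel $i$ records

$$y_i(t) = b_i + d\,\tfrac{t}{3600} + g_i\, a(t_k)^{p_i}\, g(\tau) + \varepsilon,$$

with per-channel baseline $b_i$, common linear drift $d$, gain $g_i$, and
i.i.d. Gaussian noise $\varepsilon$. The unit-peak pulse kernel $g(\tau)$ is
zero during a 30 s pre-injection idle (which is what makes a baseline
estimate possible), rises linearly over `pulse_rise` seconds while the pump
runs, and decays exponentially with time constant `pulse_decay` during
flushing; its closed-form maximum `min(injection_duration/pulse_rise, 1)` is
used by the tests. The amplitude is frozen at the cycle start. The
channel-specific response exponents $p_i$ (default 1.0, 0.7, 1.3) reflect the
power-law response curves of MOS sensors; they also ensure the three channels
carry linearly independent information — with equal exponents the noiseless
channels would be exact scalar multiples and no multi-channel regression
would be identifiable.

**Offline sampling and gaps.** Hourly offline values carry Gaussian noise
(pH sd 0.033, treating the instrument's ±0.1 pH accuracy as a 3σ band; TTA sd
0.1). Acquisition crashes are modelled as fully missing cycles via
`gap_spec`; missing cycles are absent rows, never sentinel values. All
randomness flows from the config's seed through an RNG scope that restores
the caller's stream, so identical configs reproduce runs bit for bit.

**What the generator does not emulate:** microbial population dynamics,
substrate (sugar) depletion chemistry, sensor cross-sensitivity to humidity
and temperature, nonlinear drift, or the parabolic pH curves occasionally
seen in practice. Passing tests therefore demonstrate correctness of the
algorithms under the stated generative assumptions, not field performance on
real doughs.

## Feature extraction

Cycles are segmented by the *clock* (sample $j$ belongs to cycle
$\lfloor t_j/\text{cadence}\rfloor$), not by peak detection, because the
instrument cycle is clock-driven; gaps leave holes in the index sequence. A
segment is retained if it has at least 20 samples and its samples span at
least `cadence − tolerance` seconds (tolerance defaults to a tenth of the
cadence, absorbing sampling jitter); dropped segments are reported.

Per channel, the baseline BL is the median of the first `n_pre = 5`
pre-injection samples (median for spike robustness), the peak height PH is
the raw maximum, and the peak area PA is the trapezoidal integral over the
segment's sample times. PH and PA are stored *raw* with BL alongside; the
calibration equations subtract the baseline at regression time (for areas,
the baseline-equivalent area `BL · cadence`). Any constant convention shift in
this subtraction is absorbed exactly by the regression intercept, a property
pinned by a dedicated test, so predictions do not depend on the choice.

## The three calibration methods

All three regressions minimise the sum of squared errors; closed-form
ordinary least squares (`stats::lm`) is used because it is the exact
minimiser of that objective and is deterministic. Rank-deficient designs
abort with the collinear channels named rather than silently dropping terms.

1. **Sensor-signal method.** Features are matched to the offline sampling
   times (nearest cycle midpoint, ties toward the earlier cycle; samples
   farther than half a cadence from any retained cycle are dropped with a
   warning) and
   $C = K_1 + K_2(PH_{822}-BL) + K_3(PH_{813}-BL) + K_4(PH_{MQ3}-BL)$ is
   fitted on the matched pairs (peak-area analogue: $K_5 \dots K_8$). At
   least 5 pairs are required for the 4 coefficients.

2. **PCA regression method.** The six features (PH and PA per channel) are
   autoscaled — centred and divided by the *population* (denominator-n)
   standard deviation, a choice that makes row duplication leave loadings and
   coefficients exactly unchanged — over **all** retained cycles of the
   fitted dataset, and projected on the first two principal axes.
   $C = K_9 + K_{10} PC1 + K_{11} PC2$ is then fitted on the offline-matched
   rows only. Whether the basis should instead be restricted to the matched
   rows is genuinely open; `fit_rows = "matched"` switches to that reading.
   Zero-variance (dead-sensor) features are dropped with a warning and their
   loadings padded with zeros.

3. **Interval method.** Each retained cycle's three channels are resampled to
   `L = 60` points by linear interpolation, concatenated into a 3L shape
   vector, mean-centred across cycles, and scored on the first principal
   axis; the offline target is interpolated linearly to the cycle midpoints
   (constant beyond the sampled span) and $C = K_1 + K_2 PC1$ fitted over all
   cycles. Only the first component is used: on pulse-shaped cycles it
   carries essentially all shape variance (typically > 99%) and further
   components mostly add noise. The attained explained variance is stored on
   the model. An all-identical cycle matrix is a degenerate-score-variance
   error, not a silent zero fit.

**Sign convention.** Every principal axis is flipped so its
largest-magnitude loading entry is positive. Without this, refitting on
identical data could return sign-flipped scores and coefficients; with it,
fits are bitwise reproducible and coefficients comparable across runs.

**Pooled (grouped) models.** `pool_runs()` concatenates the rows of several
runs; fitting on a pool uses one shared autoscaling/PCA basis and one
coefficient vector, which is how grouped same-temperature models and
cross-temperature combinations are built in `table2_design()`.

## Evaluation and transfer validation

References are the offline values interpolated linearly onto the retained
cycle midpoints (constant extrapolation at the ends): nominally 120 points
for a gap-free 10 h run, fewer when gaps reduce n. Metrics are
$SSE = \sum(pred-ref)^2$, $RMSE = \sqrt{SSE/n}$, and the percentage error
$100 \cdot RMSE / (\max ref - \min ref)$ — "range" read as max − min of the
reference series on the evaluation grid, which makes pH and TTA errors
comparable. A zero range yields an explicit NA with a warning. R² is the
squared Pearson correlation of predicted vs measured; it is computed for any
method on request, though for the PCA-based methods score scatter makes it a
weak diagnostic.

Transfer validation ("TARGET with SOURCE") inserts the source model's
coefficients into the target dataset's regression equation. The target's own
transformation basis — its baselines, and a PCA refitted on the target for
methods 2–3 — is the default (`basis = "target"`), because coefficients are
only meaningful relative to some basis and an online deployment would have
the target's own cycles available; `basis = "source"` instead applies the
source's stored transformation unchanged. Self-validation reproduces
self-calibration exactly under either basis, a pinned invariant.

## Campaigns and reproducibility

`run_campaign()` orchestrates simulate → extract → fit → evaluate → validate
from one `campaign_config()`, writing per-run CSVs, JSON model files and
metrics tables; `table2_design()` builds the canonical 16-run,
three-flour × three-temperature study with its same-temperature pools,
cross-temperature combinations, and 30 °C validation targets. Per-run seeds
derive from the global seed by a stable 31-bit hash of the run id, so a
campaign is reproducible end to end while runs remain mutually independent.
The package API (these functions plus the I/O layer) is the intended
interface for scripted studies; there is no separate shell executable.

## Numerical choices and degenerate inputs

- Interpolation everywhere is `stats::approx` (linear, `rule = 2` constant
  extrapolation); integration is `pracma::trapz`.
- Baseline estimation requires ≥ 3 pre-injection samples; segments with
  fewer than 20 samples are dropped and reported.
- PCA degeneracy thresholds: features with population sd below 1e−12 are
  treated as constant; a first principal axis with sdev below 1e−12 is a
  degenerate-score-variance error.
- Model files are version-tagged JSON storing the full transformation
  (center, scale, loadings) with the coefficients, because PCA coefficients
  are meaningless without their basis; a reloaded model predicts identically
  to the saved one.
- Trace/offline/feature CSVs are written with 17 significant digits so
  read-after-write is an identity at double precision; parse errors name the
  file, column and row.

## Problem sizes used in the tests

The shipped suite simulates runs of 1–10 h at 1 Hz (up to 120 cycles of 300
samples), campaigns of up to 16 runs, 20-replicate noise studies, and
20-matrix oracle comparisons; these sizes were chosen as the smallest that
exercise each property convincingly.

## Known limitations

- The affine TTA law cannot produce the saturating TTA tails seen in long
  fermentations; the logistic pH law cannot produce parabolic pH curves.
- Calibration is strictly linear: no regularisation, no nonlinear links, and
  no combined height+area regression (single-feature models are fitted
  separately).
- Drift is compensated only implicitly (through per-cycle baselines), not
  modelled or corrected explicitly.
- The interval method's score is only identified up to the stated sign
  convention; comparing coefficients against other software requires
  aligning conventions first.
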