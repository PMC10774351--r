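---
title: "Linking oscillatory EEG power to the vividness of imagined experiences: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking oscillatory EEG power to the vividness of imagined experiences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

People differ enormously in how intensely they experience voluntary mental
imagery, from aphantasia (no imagery at all) to hyper-phantasia. Because
imagined experiences are thought to be driven by feedback into sensory
cortex, the power of oscillatory brain activity at specific frequencies is a
natural candidate neural correlate of that subjective intensity. vividEEG
implements a complete analysis chain for a within-participant EEG design
with three interleaved trial types — imagined audio, imagined visual and a
resting state, recorded with eyes closed — plus a 1–5 vividness rating after
every imagery trial:

1. per-trial power spectral density (PSD) features, 1–40 Hz per sensor;
2. a per-participant leave-one-trial-out nearest-neighbour condition
   decoder with a label-shuffle significance test (a compliance check:
   can we tell from the PSD what the participant was doing?);
3. group-level cluster-based permutation tests for condition differences
   over sensor × frequency space;
4. per-frequency support-vector regression (SVR) of participant vividness
   ratings on global imagery-minus-rest power differences, validated
   against a shuffled-label chance distribution with
   Jeffreys–Zellner–Siow (JZS) Bayes-factor t-tests.

Because raw EEG from such a study is large and not redistributable, the
package ships a synthetic-cohort generator with a fully known ground truth;
every downstream stage is tested against quantities that were planted by
construction.

# The synthetic generator

`syntheticConfig()` defaults describe the emulated session: 44
participants, 18 trials in each of 3 conditions, 64 sensors in the standard
BioSemi extended 10–20 layout, 1024 Hz sampling, 10 s trials.

Signals are composed in the frequency domain. The expected one-sided power
in each FFT bin is

\[ S(f) = P_0 \, \max(f, 0.5)^{-a} + P_\alpha \exp\!\big(-(f - f_\alpha)^2 / 2\sigma_\alpha^2\big), \]

a 1/f^a background (default \(a = 1\), \(P_0 = 10^{-12}\,\mathrm{V^2}\) per
bin, floored below 0.5 Hz) plus a Gaussian alpha peak (default
\(f_\alpha = 10\) Hz, \(\sigma_\alpha = 1.5\) Hz, \(P_\alpha = 2 \times
10^{-12}\,\mathrm{V^2}\) — prominent, as expected for eyes-closed
recordings). The waveform is realized with independent complex-Gaussian
coefficients per FFT bin, sensor and trial, so band-limited components are
noise-like rather than additive sinusoids. These scales put the signal RMS
near 10–15 µV, comfortably below the 250 µV artifact range.

Condition effects are *multiplicative* factors on band-limited power:
imagery reduces broad-band power relative to rest with a stronger alpha
reduction, maximal at occipital sensors. Topographic weighting maps a
factor \(m\) at sensor weight \(w_s \in [0.3, 1]\) (largest at the most
posterior sensor, linear in the anterior–posterior coordinate) to a per-
sensor factor \(1 + (m-1) w_s\) — every sensor carries some effect, the
occiput the most. The defaults make the three conditions pairwise
distinguishable: audio imagery scales 1–24 Hz by 0.90 and 8–12 Hz by 0.75;
visual imagery scales 1–10 Hz by 0.88 and 8–12 Hz by 0.65.

Vividness is latent and continuous: per participant, uniform on [1, 5] via
a Gaussian copula with correlation 0.7 between the audio and visual
modalities (strong audio–visual vividness correlations are a robust
empirical finding). Reported per-trial ratings add Gaussian noise (SD 0.25)
and round onto the 1–5 scale; rest trials are unrated. A vividness
*coupling* multiplies band power on imagery trials by
\(\exp\{\beta (v - 3) + \varepsilon\}\), \(\varepsilon \sim N(0,
\sigma_c)\), so \(\beta\) is exactly the slope of imagery-minus-rest log
band power per rating unit — the quantity the recovery tests regress for.
Defaults couple audio vividness to 6–9 Hz and visual vividness to
14–16 Hz with \(\beta = -0.12\) (more vivid, larger reduction).

Artifacts, when enabled, are in-band (5 Hz, Gaussian-windowed, 0.5 mV)
excursions added to randomly chosen (trial, sensor) cells and recorded in
the ground truth; being in-band they survive filtering, so the amplitude
screen downstream must recover exactly the injected cells.

What the generator does **not** emulate: spatial correlation between
sensors (each is independent noise), volume conduction and realistic
topographies beyond the posterior gradient, eye movements and other
ICA-separable artifact structure, non-stationarity within trials, and
condition-dependent rating distributions. Passing tests therefore
demonstrate correctness of the analysis chain and recoverability of planted
effects, not realism of any particular electrophysiological claim.

# Preprocessing

The pipeline order is fixed: **filter → average-reference → epoch →
amplitude screen**, so filter transients never sit at epoch boundaries.

Filtering is a 6th-order Butterworth band-pass (1–100 Hz, realized as
cascaded high- and low-pass sections) plus a 6th-order 45–55 Hz band-stop,
applied forward–backward (two-pass, zero-phase). Numerically the design is
kept in zero-pole-gain form and factored into second-order sections: a
6th-order high-pass at 1 Hz on kHz-rate data has all poles within 2×10⁻³ of
z = 1, where expanded transfer-function coefficients lose the poles'
accuracy. Edges use odd-reflection padding with DC-steady-state initial
conditions per section (so constant inputs pass with exactly the DC gain);
the padding default is 3 × 20 samples per section. A reflected mid-phase
sinusoid necessarily has a derivative kink at the boundary, so a pure tone
retains ~1% broadband energy within a filter time-constant of the edges —
the same behaviour as other section-based forward–backward implementations
— which is immaterial here because epoching discards 0.5 s at each end.

Epoching keeps the centred `epochDuration` (default 9 of 10 s); a
fractional margin is floored on the left for determinism. The amplitude
screen excludes any (trial, sensor) whose within-epoch peak-to-peak range
exceeds a threshold, default 250 µV. (The source description of this
criterion prints "250 mV", which is not a plausible scalp-EEG amplitude; we
read it as microvolts and expose the threshold as a parameter so either
reading is reproducible.) Manual ICA-based artifact rejection is *not*
reproduced — it requires visual inspection — and the amplitude screen is
the only exclusion; this is a documented fidelity gap.

# Spectral features

Power is the bare one-sided periodogram of the whole epoch — no taper, no
segment averaging, since the subsequent 1 Hz binning already smooths: at
frequency index \(k\), \(P_k = |X_k|^2 \cdot 2 / N^2\) (DC and Nyquist not
doubled), so an on-bin sinusoid of amplitude \(A\) carries \(A^2/2\) and
the spectrum sums to the signal's mean square exactly (Parseval tests are
exact to rounding). Bin \(f \in \{1, \dots, 40\}\) Hz averages the FFT
frequencies that round (half-up) to \(f\), i.e. \([f-0.5, f+0.5)\); a 9 s
epoch contributes 9 FFT frequencies per bin. Screened cells are NaN across
all 40 bins and stay NaN-aware through every downstream mean. Absolute
power units are irrelevant downstream (everything is differences,
rank-free distances, or regression), so no density normalization is
applied.

# Decoding

Features are the full sensor × frequency PSD of a trial. A conditional
signature is the NaN-aware mean over all *other* trials of a condition
(leave-one-trial-out; the decoded trial never contributes to its own
template). The decision rule is the smallest **sum of absolute
differences** over cells finite in both trial and signature — deliberately
not Euclidean distance and with no rescaling. Exact ties (measure zero for
continuous features) go to the first condition in the fixed order audio,
visual, rest. Trials sharing no finite cell with some signature are
undecodable and leave the success-rate denominator. The shuffle test
permutes labels within participant, re-runs the entire leave-one-out
decode, and reports the add-one estimator
\(p = (1 + \#\{\text{shuffled} \ge \text{actual}\}) / (n_\text{shuffles} + 1)\).
Cohort summaries test participant success rates against chance (1/3) with
a one-sample t and JZS Bayes factor.

A subtlety the calibration tests quantify: under a true null the
leave-one-out construction is very slightly pessimistic (the true class's
training set is one trial smaller, so its signature is a touch noisier and
farther in expected absolute distance); at 18 trials per condition the mean
success sits ≈ 0.005 below 1/3, well inside the ±0.02 acceptance band.

# Cluster-based permutation tests

Per participant and condition, PSDs are averaged over trials; group
outliers (beyond ±3 SD of the across-participant mean for that sensor ×
frequency × condition cell, mean and SD computed *including* the point, as
a plain reading of the procedure implies) are replaced by the mean of the
participant's spatially adjacent sensors at that frequency, or NaN when no
neighbour is finite. Note an arithmetic consequence of the inclusive
statistics: with \(n\) participants no point can exceed
\((n-1)/\sqrt{n}\) inclusive SDs, so the 3-SD rule can only ever fire for
\(n \ge 11\); at the design size (44) this is immaterial.

Sensor adjacency defaults to a Delaunay triangulation of the montage
projected azimuthal-equidistantly to the plane (computed by brute-force
empty-circumcircle testing — at 64 sensors this is instant and needs no
geometry library), and an explicit 0/1 adjacency file can override it.
Two sensor × frequency points are neighbours when their frequencies differ
by ≤ 1 Hz and they are the same or adjacent sensors. Paired t maps use
pairwise-complete participants per cell; cells are thresholded two-sided at
the cluster-forming α (default 0.05), positive and negative t clustered
separately, and each cluster's mass is its summed t. The null is the
distribution of the maximum |mass| under within-participant condition
exchange — sign-flips of the paired differences. When \(2^n \le
n_\text{perm}\) all sign patterns are enumerated and p-values are exact
proportions; otherwise random flips with the add-one estimator. Family-wise
error under the null is verified ≤ 0.08 at α = 0.05 over 200 simulated
cohorts.

# Per-frequency SVR with a shuffled-label chance distribution

For each imagery modality the feature is *global*: the imagery-minus-rest
difference PSD (from the outlier-treated condition means) averaged over all
sensors, one value per participant per frequency. Per frequency, 125
iterations of fourfold cross-validation (participants randomly
re-partitioned into equal groups each iteration; the participant count must
divide by the fold count, mirroring the 44 = 4 × 11 design) fit a linear
ε-insensitive SVR of ratings on the single feature — feature and target
z-scored by training-fold statistics; C = 1, ε = 0.1, the common defaults,
exposed as parameters — and record the Pearson correlation between
predicted and actual held-out ratings, giving 500 fold R-values; a matched
set with ratings re-shuffled before every partition gives 500 chance
R-values. Degenerate folds (zero variance anywhere) record R = 0 so the
bookkeeping stays exact. A two-sample JZS Bayes-factor t-test per frequency
compares actual against chance, and maximal runs of ≥ 2 consecutive
frequencies with BF₁₀ ≥ 100 are reported as predictive bands.

**A documented limitation.** The 500 fold R-values at one frequency share
participants across iterations and are far from independent, yet the
two-sample test treats them as samples — this is the procedure as defined,
reproduced as-is. The consequence is quantifiable: with one linear feature,
a fold's predictions are affine in the feature, so the fold R-value is
±(held-out empirical correlation), and the mean of the 500 values tracks
the *dataset-level* sample correlation, which wanders with SD ≈ 1/√n
across null datasets, while the shuffled mean stays pinned near its small
negative bias (train and held-out correlations of a fixed dataset are
anti-correlated under resampling). Dividing that wander by a standard
error that shrinks like 1/√500 manufactures extreme t values: at the
design scale, the large majority of truly null frequencies reach
"extreme evidence" (BF₁₀ ≥ 100). The acceptance suite asserts the intended
calibration bounds and documents that the method as defined does not meet
them; treat discovered bands as descriptive unless the chance distribution
is constructed at the dataset level (e.g. permuting ratings once per
dataset replicate), which is outside the reproduced procedure.

# JZS Bayes factors

Both t-tests use the Jeffreys–Zellner–Siow default prior: Cauchy
(scale \(r = \sqrt{2}/2\), configurable) on the standardized effect,
Jeffreys on the variance. Writing the Cauchy as a normal-scale mixture with
an inverse-gamma(1/2, r²/2) mixing density leaves a one-dimensional
integral over the mixture parameter \(g\), evaluated on the log-g scale,
centred at the integrand's mode and integrated adaptively (relative
tolerance 10⁻¹⁰); the Bayes factor is assembled in log space, so
overwhelming separations (t in the tens) return astronomically large but
finite values and only genuinely out-of-range evidence returns Inf. The
two-sample test uses effective sample size \(n_1 n_2/(n_1+n_2)\) and
\(df = n_1 + n_2 - 2\); the per-frequency comparison is an independent
two-sample test since the 500 + 500 values carry no natural pairing.
Reciprocity (BF₁₀·BF₀₁ = 1), scale invariance, the BF → 1 limit as the
prior scale vanishes, and 4-significant-figure agreement with a fixed-grid
Simpson quadrature and with an independent reference implementation are
all under test.

# Orchestration and reproducibility

`runPipeline(pipelineConfig(...))` executes synthesis (streamed
participant-by-participant straight to PSD features; the full-scale raw
cohort would be ~12 GB), decoding, the three pairwise cluster tests, and
both modality SVR analyses, writing stage CSVs and one JSON summary. Every
stochastic stage consumes its own child seed, derived from the master seed
by a fixed counter formula (`childSeed`), so a stage's results do not
depend on whether earlier stages changed their internal draw counts.
Identical seeds give byte-identical cohorts and summaries. The package is a
library rather than a shell tool; the pipeline and each stage are exported
functions, and `inst/scripts/run_pipeline.R` is a thin command-line wrapper
over them for users who want one.

On-disk formats are deliberately simple: an RDS container of trial voltage
matrices grouped by participant (no HDF5 binding is assumed), CSV trial
metadata, whitespace-delimited montage text, and long-form CSV export of
PSD features.

# Problem sizes used by the test and acceptance suites

All statistical properties are asserted at reduced but statistically
meaningful sizes, chosen once as a matter of test design: chance-level
decoding on 88–120 condition-uninformative participants at 8 sensors /
256 Hz (the null success rate does not depend on dimensionality);
shuffle-test calibration on 200 pure-noise participants; cluster
family-wise error on 200 ten-participant cohorts; coupling-slope recovery
on 20 seeds of 44 participants with 2 sensors and 2 s trials; planted
occipital alpha recovery on 20 participants × 16 sensors; planted-band SVR
recovery on 20 seeds of 16 participants with 15-iteration resampling. The
full-scale defaults (44 × 54 trials × 64 sensors × 1024 Hz) run through
the same code paths and are exercised structurally on single participants.

# Known limitations

- No ICA artifact separation; the amplitude-range screen is the only
  exclusion.
- Sensors are simulated as independent noise sources; topographic effects
  are power weightings, not a forward model.
- The per-frequency Bayes-factor comparison inherits the fold-R
  non-independence problem described above.
- Absolute PSD units are not calibrated to any recording system; only
  shapes, contrasts and regressions are meaningful.
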