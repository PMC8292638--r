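---
title: "Detecting vicarious trial and error from trajectories and hippocampal oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting vicarious trial and error from trajectories and hippocampal oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Vicarious trial and error (VTE) is the pause-and-look vacillation a rodent
shows at a decision point: instead of sweeping smoothly into the chosen arm,
the animal advances partway toward one option, reverses, reorients, and may
repeat the cycle before committing.  VTEs are widely used as a behavioral
marker of deliberation, but hand-scoring them is slow and the classical
single-metric detector — a threshold on zIdPhi, the session-z-scored
integrated change in heading angle — draws no sharp boundary between VTE and
non-VTE trials.  `vtekit` implements a multi-feature alternative: a small
set of trajectory descriptors, a parallel set of hippocampal field-potential
descriptors, balanced seeded cross-validation with k-nearest-neighbor (KNN)
and radial-basis-function support vector machine (RBF-SVM) classifiers, and
a chance-referenced evaluation layer.  A built-in plus-maze and LFP
simulator makes every stage testable without recorded data.

## Trajectory features

For each choice-epoch head trace $(x_i, y_i)$ the package computes:

* the heading angle $\varphi_i = \operatorname{atan2}(\Delta y_i, \Delta x_i)$
  of successive displacements, and IdPhi $= \sum_i |\Delta \varphi_i|$, the
  integrated absolute heading change.  Angular differences are wrapped to
  the shortest circular distance in $[0, \pi]$ by default: the raw
  difference $|\varphi_a - \varphi_{a-1}|$ would count a crossing of the
  $\pm\pi$ discontinuity as a near-full turn.  The unwrapped behavior is
  selectable (`wrap = FALSE`) for strict backward comparability.
* zIdPhi, the per-session z-score of IdPhi (population SD, divisor $N$ —
  matching the numerical convention of the array library the feature set
  was originally built on).  Session-wise scoring absorbs differences in
  camera geometry and running speed.
* the positional SDs $x_\sigma$, $y_\sigma$ (population SD).
* the dwell time within an experimenter-defined choice-point polygon
  (default: the simulator's center platform, a 30-unit square).
* $r^2 = 1 - SSE/SST$ of a degree-6 least-squares fit of $y$ on $x$.  Smooth
  single-pass arcs fit nearly perfectly; VTE zig-zags do not.  The abscissa
  is centered and scaled before building the Vandermonde system purely for
  conditioning; $r^2$ is unchanged by that affine map.
* $n_{coef}$, the number of discrete Fourier magnitudes (largest first,
  conjugate pairs counted once) needed to capture 95% of the fit estimate's
  spectral energy.  The fit estimate is linearly detrended first: without
  detrending, any non-periodic ramp needs $\mathcal{O}(10)$ coefficients
  purely from the sawtooth spectrum of its periodic extension, which would
  swamp the oscillatory structure the feature is meant to count.  A straight
  path scores 0, a single oscillation 1, damped-oscillation-like VTE fits
  several.  The 95% energy fraction is exposed as a parameter; no published
  rule exists for this cutoff, and 0.95 is the single interpretable knob we
  commit to.

Seven features enter the classifier.  The published description announces
seven but lists six; we include raw IdPhi alongside zIdPhi as the seventh
(it is the only already-computed per-trial candidate) and expose
`include_idphi` to drop it.

## Oscillation features

Field potentials are decimated from 30 kHz to 1 kHz (anti-alias filtered;
plain subsampling selectable) and z-scored over the entire session, so
amplitude is in SD units.  Theta cycles are segmented on an 80 Hz zero-lag
(forward–backward) Butterworth lowpass: local maxima at least 0.0833 s apart
(the 12 Hz upper edge of theta) are peaks, the minimum between consecutive
peaks is the trough (earliest sample on ties), and a cycle runs
peak → trough → next peak.  No upper bound is placed on cycle duration by
default (only the minimum separation is published); a cap is exposed as
`max_duration`.  Per cycle the asymmetry index is

$$AI = \log(\text{asc}) - \log(\text{desc})$$

with the natural log (the base only rescales AI; natural log is the
convention of the prior work the feature comes from).  Gamma power comes
from third-order zero-lag Butterworth bandpasses at 35–55 Hz (low) and
61–100 Hz (high), re-z-scored, with instantaneous power $p(t)$ the squared
modulus of the analytic signal.  The per-cycle gamma ratio GR is the
cycle-averaged low-gamma power over the cycle-averaged high-gamma power;
power is averaged within cycles *before* trial-level aggregation, so trial
features are cycle-weighted rather than sample-weighted (the published
"cycle-averaged" phrasing is ambiguous; we commit to cycle weighting and
note that sample weighting differs only when cycle durations vary).  Twelve
features describe a trial epoch: mean and SD of AI, GR, low- and high-gamma
power and cycle duration, plus mean ascending and descending durations.

Two practical points matter here.  First, gamma normalization must happen at
the *session* level: z-scoring per trial segment fixes every segment's band
variance at 1 and erases exactly the between-trial power differences the
features are supposed to carry.  `session_osc_features()` therefore filters
and normalizes the whole session trace once and slices afterwards;
`extract_osc_features()` on an isolated segment is provided for
completeness.  Second, the periodogram features (Hamming taper over the
whole segment, 1 Hz bins, 1–100 Hz, powers kept linear rather than in dB)
are selected per frequency by two-sample two-tailed Kolmogorov–Smirnov tests
with Benjamini–Hochberg correction at 0.05 — and this selection runs on
training data only within each cross-validation split, a leakage guard the
original description does not spell out.

## Curation

Four raters vote per trial; a 3–1 or 4–0 majority defines the consensus
label and 2–2 ties are excluded (majority is the only consistent completion
of the published tie rule).  Inter-rater quality is summarized by pairwise
percent agreement and Cohen's kappa over the six pairs.  Trials whose
analyzed epoch exceeds 4 SD (SD of the entire session timeseries — we apply
the threshold to the full z-scored trace, not a band-limited copy) are
excluded, a session loses all data when *strictly more than* 20% of its
trials are excluded, and the session-level theta-asymmetry distribution must
skew in the dataset's direction (positive here; recording sites along other
hippocampal axes legitimately skew negative, so the required sign is
configurable).

## Classification and evaluation

Because VTEs are ~20% of trials, each of 100 seeded split columns contains
every consensus-VTE trial plus an equal number of non-VTE trials sampled
without replacement; the shuffled column's first 67% trains
(`floor(0.67 n)`, a deterministic boundary) and the rest tests.  The same
matrix is reused for every model and feature modality, so all comparisons
are paired split-by-split.  Features are standardized on training statistics
only.  KNN uses $k = 5$ Euclidean neighbors and scores a query by its
neighbors' VTE-vote fraction (the published work plots KNN ROC curves
without defining a score; the vote fraction is the natural choice).  The
RBF-SVM searches $\gamma \in \{0.01..0.1\ \text{by}\ 0.01\} \cup
\{0.2..1\ \text{by}\ 0.1\}$ and $C \in \{0.1..1\ \text{by}\ 0.1\} \cup
\{2..10\ \text{by}\ 1\}$ — 361 pairs — by internal 5-fold cross-validated
AUC on the training portion, with ties broken toward the smallest $C$ then
the smallest $\gamma$.  Hyperparameters are selected once per feature table
(on the first split's training portion) and reused across the 100 splits:
the published procedure optimized per data type, and selecting on held-out
data would leak.  No SVM or KNN implementation ships with this R stack, so
both are authored here; the SVM dual quadratic program is solved with
`quadprog`.

Evaluation uses accuracy, precision, recall and the false negative rate
from the confusion counts (undefined ratios are reported as `NA`, never 0),
and ROC/AUC by threshold sweep with trapezoidal integration, which equals
the Mann–Whitney concordance probability with ties counted one half.  The
ROC abscissa is the conventional false *positive* rate: the published text
says "false negative rate", but its own FNR formula and the shape of its
ROC figures are consistent with the conventional axis, so we implement that
and note the discrepancy.  Chance is estimated by rerunning the identical
pipeline with balanced uniformly random training labels; Δ scores are
per-split differences from that baseline, so zero means chance-level.
Distribution comparisons use two-sample two-tailed KS tests (asymptotic
p-values by default, exact on request), paired comparisons use one-sample
two-tailed Wilcoxon signed-rank tests, families of tests are BH-corrected,
and effect sizes are pooled-SD Cohen's d (the variant is unstated in the
source; pooled is the common default).

## The simulator: what it states, and what a green test establishes

`sim_config()` states the world: 60-trial sessions, 20% VTEs, 35 Hz
tracking, 1 kHz LFP with 8 Hz theta.  Non-VTE trajectories are smooth
cubic-Bezier arcs from the start-arm tip through the center platform to the
chosen arm (~2 s); VTE trajectories insert 1–3 head sweeps toward the
unchosen arm (~0.8 s each) at the center; Gaussian tracking noise of 1 maze
unit per frame gives zIdPhi distributions that overlap between classes, so
the single-metric baseline is imperfect and the multi-feature comparison is
non-trivial.  Theta asymmetry is produced by a smooth monotone phase warp
$v(u) = u - A(1-\cos 2\pi u)/2\pi$ with $A$ chosen in closed form so the
trough falls at the target descending fraction $1/(1+e^{AI})$; the warp
preserves the period exactly and keeps the waveform locally symmetric about
each landmark.  An earlier piecewise-linear warp put a slope kink at every
peak, and the 80 Hz lowpass rounded the kink asymmetrically, displacing
detected peaks into the flatter flank and attenuating recovered AI — the
smooth warp removes that artifact at the source.  For the same reason the
gamma bursts are centered on the *symmetric* cycle landmarks (low gamma at
the trough, high gamma at the peak): centering a burst on the ascending
flank measurably biases the landmark-based AI estimator (−0.18 at a true AI
of 0 in our measurements), which would break the simulator's own recovery
property.  Burst carriers are 45 and 80 Hz, amplitudes set by
class-conditional power targets (defaults: low gamma ×1.5 and high gamma
×0.85 on VTE trials, AI 0.20 vs 0.10), and broadband 1/f noise is added at
0.15 SD relative to unit theta — the emulated recordings are fissure sites
explicitly selected for high-amplitude theta, which is why the noise floor
is low.  Rater votes flip truth independently at 5% per rater, which
reproduces >90% agreement and kappa >0.7.  Class-conditional LFP effects
are injected in the choice epoch only by default, so delay-epoch features
are uninformative, as observed in the system this emulates.

What the generator does *not* emulate: tracking dropouts (real data have
them; the readers flag rather than interpolate, and feature code decides),
non-stationary theta frequency, inter-animal variability, volume-conducted
artifacts, and any spike-level structure.  A green pipeline test therefore
establishes that the algorithms recover what this stated world contains —
not that the defaults match any particular animal.

Two measurement properties are worth knowing and are themselves asserted by
tests.  Under the default noise the landmark AI estimator attenuates
(~8% at AI 0.3): additive noise displaces the detected peak toward the
flatter flank.  And absolute gamma power and GR carry estimator-level
factors — third-order Butterworth attenuation of the 45 ± 8 Hz AM sidebands
near the 35/55 Hz band edges, filtfilt warm-up in boundary cycles — that
are common to both classes.  Parameter-recovery checks therefore run the
identification configuration (noise off) for absolute values and assert
*class ratios* at the stated world, which is also the only scale that
survives session-level normalization.

## Numerical choices

Half-open `[start, end)` epoch windows make slicing a partition.
Timestamps are stored in seconds (the acquisition's millisecond timer is
converted on read); positions stay in camera pixels (nothing is physically
calibrated upstream).  Butterworth filters are designed by bilinear
transform and validated against an independent reference implementation to
coefficient-level agreement; forward–backward application uses odd
reflection padding with steady-state initial conditions.  The analytic
signal pads to the next 5-smooth length by odd reflection before the FFT
(mixed-radix FFTs degrade badly on prime lengths) and truncates afterwards.
Trough ties break to the earliest sample.  Zero-spread features are dropped
with a warning at standardization.  The SVM dual adds a 1e-8 ridge for
positive-definiteness; its intercept averages over margin vectors, falling
back to the KKT midpoint when no vector sits strictly inside the box.
Session structure places each trial's delay *after* its choice and return
epochs; the delay that precedes a given choice is thus the previous trial's
delay window, and because no class effect is injected there, either pairing
yields an uninformative delay feature set.

## Known limitations

The single-session world is the unit of simulation; criterion-level
comparisons pool several simulated sessions because a single finite session
carries chance feature–label correlations that split-resampling cannot
remove (splits resample the same trials).  The zIdPhi threshold scan
selects the 50th–80th percentile maximizing the two-point ROC area on
training data; on small samples that selection is optimistically biased —
the package reports what the procedure yields, as published.  Hyperparameter
selection reuses one grid search per feature table; per-split searches would
multiply runtime ~100-fold for no change in the paired comparisons the
design supports.
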