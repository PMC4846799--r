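---
title: "Decoding motor intention for neuroadaptive flight automation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor intention for neuroadaptive flight automation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific and numerical choices behind
`neuroadapt`: what the pipeline computes, what the synthetic-data generator
does and does not emulate, and where design decisions were genuinely open.

## The problem

A pilot holding a control stick reacts to a sudden attitude perturbation
(an abrupt pitch-down) in roughly 360–430 ms. Neural activity related to the
*intention* to recover precedes the hand movement, so a passive
brain–computer interface that detects this intention from multichannel
recordings can, in principle, trigger the recovery maneuver tens of
milliseconds before the stick moves. The package simulates this off-line and
in open loop: decoders are trained on two sessions of a simple piloting
task (straight, level flight; the participant chooses per trial whether to
fly or passively watch), evaluated on a third held-out session of the same
task, and then transferred to a complex piloting task (continuous
visuomotor control through terrain) that neither the decoder nor its
features were tuned on.

The two training classes are *active perturbation* trials (fly, recover)
versus *passive perturbation* trials (watch the same visual event without
moving). Training on perturbation-present versus perturbation-absent trials
instead would mostly capture the visual evoked response, which cannot
generalize to a task whose visual field changes continuously; the
fly-versus-watch contrast targets the attentional/motor-intention component.

## The synthetic subject

Real recordings of this protocol are not publicly distributed, so the
generator (`simulateSubject()`) reproduces the study conditions with planted
ground truth:

* **Sessions and trials.** Three simple-task sessions and one complex-task
  session. Simple sessions have 90 trials; piloting is chosen with
  probability 2/3 and a perturbation occurs on 67% of trials, giving the
  protocol's average 40/20/20/10 condition mix. The complex session has
  exactly 60 perturbation and 30 no-perturbation trials in random order.
  Perturbation onset is uniform in 2–4 s; no-perturbation trials receive a
  virtual onset the same way (the photodiode convention).
* **Sources and mixing.** Each subject has one task source, one ocular and
  one cardiac artifact source, and five ongoing background sources
  (burst-modulated narrowband noise at 5–22 Hz; the bursts make them
  super-Gaussian, the regime Infomax separates). Sources project to the
  sensors through per-subject smooth pseudo-topographies (differences of
  spatial Gaussians on a planar array, unit-norm, pairwise |r| < 0.5 —
  distinct cortical patches). The mixing is shared by all of a subject's
  sessions, which is what lets training-session weights transfer.
* **The task source.** On perturbation trials it carries a biphasic evoked
  transient with its absolute peak at 232 ms (per-trial latency jitter
  SD 12 ms, clamped to the 190–290 ms range) — a 40 ms-wide main lobe with
  a smaller delayed rebound, chosen so the causally band-passed waveform
  keeps a single well-defined absolute peak under 300 ms. Active trials
  carry the full amplitude plus a pre-movement "readiness" ramp ending at
  the manual reaction time; passive trials carry 0.6× the amplitude and no
  ramp. The amplitude difference plus the ramp are the decodable intention
  signal. Single-trial evoked amplitude varies lognormally (SD 0.25), the
  dominant source of decoder errors in real recordings.
* **Reaction times.** Truncated normal on [200, 700] ms with means 360 ms
  (simple) and 430 ms (complex), SD 40 ms, matching the reported group
  means.
* **Noise.** Per-channel white noise (SD 0.35 relative to unit-norm source
  gains) plus a 1/f-like component; the complex task adds continuous 4–12 Hz
  visuomotor power (0.15 RMS) to the task and background sources.

The evoked amplitude (2.5), noise floor and visuomotor power were fixed once
so that the component-level single-trial SNR puts decoding performance in
the physiologically plausible range — held-out simple-task balanced
accuracies in the 60s–70s and complex-task false-alarm rates near 10% —
rather than in a trivially clean regime. What the generator does **not**
emulate: realistic sensor geometry or field spread, non-stationary artifact
topographies, inter-subject variability in source depth and orientation,
and the low, variable single-trial SNR of real MEG. Consequently the
simulated automation detects perturbations earlier and more reliably than
the original system did (synthetic time savings ≈ 200 ms versus the reported
tens of milliseconds), and passing tests demonstrate correctness of the
*procedure*, not expected performance on real data.

## Preprocessing

Filtering is a causal (forward-only) 4th-order Butterworth band-pass,
2–100 Hz at 1000 Hz — the "online" filter of a real-time system; the order
is a documented default (only the band edges are protocol constants). An
unstable design raises an error rather than silently reducing the order.
Decimation to 250 Hz keeps every 4th sample; the 100 Hz band edge sits
below the 125 Hz target Nyquist, so no extra anti-aliasing filter is
applied. Epochs span the half-open interval [−1000, +1000) ms with the
onset at 0-based sample 250 (sample k ↔ (k−250)·4 ms). Screening drops
simple-task trials for machine failures or reaction times above 700 ms and
complex-task trials only when the aircraft crashed before the perturbation
onset (post-onset crashes remain). Every drop is logged with its reason,
and trials whose onset leaves no room for a full epoch are dropped, never
padded.

## Unmixing

PCA (with whitening) reduces the concatenated training epochs to 64
components; Infomax ICA with a logistic nonlinearity and natural-gradient
block updates (block 512, initial rate 0.01) separates them. The learning
rate anneals by 0.85 whenever the update direction swings by more than 60°;
iteration stops when the relative weight change falls below 1e-7 or after
128 sweeps. With the annealed rate the sweep budget is the practical stop —
the stochastic gradient keeps the weight change of order of the learning
rate — and fit quality is therefore validated directly against the planted
ground truth: the test suite checks that the best-matching component map
correlates with the planted task topography at |r| ≥ 0.9 over ten subject
seeds. Most draws reach 0.92–0.99, but roughly one subject draw in ten has
a task source whose Infomax separation tops out near 0.86: the task source
is the weakest planted source (active only briefly on a subset of trials),
and for unfavorable geometry the Infomax optimum merges part of it with a
spatially neighboring background source. This is a limit of the objective,
not of the implementation or the data — an independent reference Infomax
implementation reproduces the same optimum to three decimals, while a
ground-truth-supervised regression recovers the map from the same data at
0.998 — so the corresponding recovery check is expected to fail for such
draws and the failure message reports the per-seed values. Component maps
are reported as activation patterns (the sensor covariance applied to the
unmixing row, i.e. the regression of sensors on the component activation),
which is the appropriate interpretation of a linear filter on noisy data;
the classical inverse-map definition is available without data.
Divergence triggers a restart at half the rate. If the data rank is
below the requested dimensionality the fit reduces to the available rank
with an explicit warning.

Weights are fitted on sessions 1–2 only and applied frozen to the held-out
sessions (`componentActivations()`), simulating online use. Each combined
unmixing row is scaled to unit norm, and the selected component's sign is
fixed so its evoked peak is positive.

The original procedure selected the evoked task component by visual
inspection; here selection is automated as the ratio of the absolute peak
of the trial-mean activation in (0, 300] ms to the baseline RMS in
[−400, 0) ms, over the active perturbation training trials. Ties break to
the lower component index. If no component's peak reaches twice its
baseline RMS the pipeline stops with a "no evoked component" error. The
spatial-map dipolarity that a human inspector would also weigh is not
scored; on synthetic data the peak-to-baseline criterion alone identifies
the planted source reliably.

## Features and the classifier

The anchor is the absolute peak (< 300 ms) of the mean evoked response of
the *first* session's active perturbation trials, on the 4 ms grid. Each
trial contributes RMS amplitudes over three consecutive 40 ms (10-sample)
windows ending 40 ms after the anchor. Passive trials are re-anchored at
120, 60 and 0 ms before onset — the third block therefore extends 40 ms
past the onset — tripling the passive rows to a ~1.5:1 passive:active
ratio. The added timing scatter deliberately biases the classifier against
false alarms and helps it generalize to the complex task.

LSPC models the class posterior as a clipped, renormalized linear
combination of Gaussian kernels centered on all training points. For class
indicator vector y the weights solve the ridge-regularized least squares
problem in closed form, θ = (KᵀK/n + ρI)⁻¹Kᵀy/n. Negative kernel sums are
clipped at zero and the two class scores renormalized; if both are zero the
posterior is uniform (which the sliding detector treats as "no intend") —
this makes the decoder conservative far from the training distribution.
Features are z-normalized with training-set statistics only; the same
statistics are frozen into the decoder for all later use. The kernel width
grid is the median pairwise training distance × {0.25, 0.5, 1, 2, 4} and
the ridge grid 10⁻³…1 (the original toolbox's exact defaults are not
published; these are documented stand-ins), selected by 5-fold
cross-validated log loss. A singular system escalates to the next ridge
value with a message, never silently.

One hundred decoders are trained that differ only in the seed of the
cross-validation fold assignment — the one stochastic ingredient of
training. Each is scored on the held-out simple session (perturbation
trials only, active vs. passive, features at the training-derived anchor)
by posterior-mean balanced accuracy, and the best is kept for the complex
task. Because the fold seed only influences the selected (σ, ρ) pair,
decoders frequently coincide; the selection is then trivial, which is the
faithful consequence of confining the randomness to fold order. No
statistic of any test session enters training or normalization.

## Online simulation and adjudication

A 120 ms window (the three 40 ms feature blocks) slides in 8 ms steps
through [0, 1000] ms after the (virtual) onset; the earliest possible
detection is therefore at 120 ms. Detection fires at the *end* of the first
window classified as intend (the start-versus-end convention is not dictated
by the protocol; the end is consistent with "earliest detection at
120 ms"). A single positive window fires by default; an optional
k-consecutive-windows rule is provided and is provably monotone (more
required windows never add false alarms and never make detection earlier).
A perturbation trial is a hit only if detection strictly precedes the
manual response; later or absent detections are misses, in which case the
automation is not engaged and the original reaction time stands with zero
savings. No-perturbation trials are scanned over the same span anchored at
the virtual onset. The mean response-time difference averages savings over
*all* perturbation trials, and altitude savings multiply it by the mean
(and greatest) per-trial descent rate, in meters.

## Evaluation statistics

*Balanced accuracy.* Sensitivity and specificity receive flat-prior beta
posteriors, Beta(tp+1, fn+1) and Beta(tn+1, fp+1); the balanced-accuracy
posterior is the distribution of their average, computed by numerical
convolution of the two densities on a 4096-point grid. The posterior mean
has the closed form ((tp+1)/(tp+fn+2) + (tn+1)/(tn+fp+2))/2 and the
interval is the central 95%. The reported `pBelowChance` is the posterior
probability that balanced accuracy is at or below 50% — a Bayesian tail
probability, documented as *not* equivalent to the original tables'
frequentist p column, whose generating computation is not reproducible from
the printed information. Note a small-sample property relevant to
calibration checks: with unequal class sizes the posterior-mean estimator
shrinks the two rates unequally, so under a null decoder biased toward one
class its expectation sits slightly above 50%; calibration tests therefore
use the raw (unshrunken) balanced accuracy.

*Signal detection.* hr = tp/(tp+fn), far = fp/(fp+tn), d′ = z(hr) − z(far),
and the nonparametric a′ (area analogue) with its symmetric complement
formula when far > hr. Degenerate rates (0 or 1) take the standard 1/(2N)
correction for the quantile only, with a note. The correction is applied
only when needed because the reported d′ values for rows with fp ≥ 1 match
the uncorrected formula; one reported row (simple task, participant 5)
prints a false-alarm rate of 0.05 with fp = 0 that no stated correction
reproduces — it is documented, not guessed, and excluded from the
reproduction tests.

*Permutation null of the savings.* Active/passive training labels are
permuted; the task component, anchor and normalization are recomputed from
the permuted labels; one decoder is retrained and the full sliding-window
adjudication re-run. Only permutations with a false-positive rate below 25%
enter the null (resampling until the requested count qualifies, with a hard
cap at 5× and an error rather than silent relaxation — the protocol is
ambiguous between filtering and coincidence, and resampling is the
conservative reading). p is the fraction of null savings at least as large
as the observed value, floored at 1/n. On the synthetic defaults the
permuted decoders false-alarm far more than the 25% screen allows (the
permuted intend class still contains strong evoked trials, pulling the
decision boundary toward the noise floor), so on synthetic signal data the
screen typically rejects everything; calibration studies on null data (no
class difference), where the screen passes, show the p-values are uniform.

*Cross-subject generalization.* The donor's feature normalization and LSPC
weights are applied to each recipient's own component activations (own
unmixing, own selected component); whether the original analysis reused the
donor's spatial weights on the recipient's sensors is ambiguous, and the
recipient-unmixing reading is the physically sensible one for
different-head geometry. Own-versus-donor per-subject means are compared
with an exact two-sided paired signed-rank test (zero differences dropped;
ties handled by enumerating the distribution of the positive-rank sum over
doubled average ranks; p = 1 when all differences are zero; NA below five
pairs).

## Problem sizes and reproducibility

One master integer seed fixes everything: session simulation, ICA sample
shuffling, fold assignments and permutations, through a deterministic
seed-derivation chain; identical configurations reproduce bit-identical
artifacts, and containers/models serialize losslessly (raw float64 +
JSON/CSV). The test suite runs the full study conditions where it matters —
64 channels for ICA recovery (ten seeds, 64-sweep budget) and for the
decoder-validity check (100 decoders) — and scaled-down problem sizes
elsewhere: 12-channel subjects with ground-truth unmixing for the decoding
chain unit tests, and 20 null replicates × 19 permutations for the
calibration study. These sizes are the package's chosen compromise between
statistical resolution and a test suite that runs in minutes.

## Known limitations

* The generator's spatial model is a planar Gaussian-patch abstraction;
  nothing about realistic MEG forward physics is claimed.
* Absolute performance numbers on synthetic data (hit rates near 1,
  ~200 ms savings) exceed what the original recordings support; only the
  procedure and its table-derived statistics are reproduced exactly.
* The ICA stops on a sweep budget in practice; component recovery is
  validated against ground truth rather than by a convergence proof.
* The LSPC hyperparameter grids stand in for unpublished toolbox defaults.
* Source localization (anatomical attribution of the selected component) is
  out of scope; the decoder does not need it.
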