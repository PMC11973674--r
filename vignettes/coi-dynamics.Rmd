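---
title: "Quantifying current-of-injury dynamics in intracardiac electrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying current-of-injury dynamics in intracardiac electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(coiwave)
library(dplyr)
```

## The problem

Pulsed field ablation (PFA) isolates pulmonary veins quickly and safely,
but gives the operator almost no intraprocedural feedback about whether a
lesion will be durable. Bipolar intracardiac electrograms (iEGMs) lose
their sharp depolarization component immediately after either PFA or
radiofrequency ablation (RFA), even when the effect is reversible, so
bipolar amplitude alone is a poor predictor of transmurality. Unipolar
iEGMs, recorded against a distant reference with a wide-open high-pass
(0.05 Hz), additionally capture a slow baseline shift after the atrial
deflection — a current of injury (COI) produced by depolarized,
transiently inexcitable tissue around the electrode. The dynamics of that
COI in the minutes after ablation carry the information this package
quantifies: after PFA the COI jumps (about +73% in the low-frequency
content at the first valid reading 30 s post-ablation) and then recovers,
and the recovery is faster and deeper for nontransmural lesions, with a
statistically detectable difference as early as 60 s post-ablation.

## Pipeline

Each lesion recording has three channels sampled at 1 kHz — a surface ECG
lead, a bipolar iEGM and a unipolar iEGM — with the ablation instant
marked. Processing proceeds in five stages.

**QRS gating.** R peaks are detected on the ECG with an adaptive
slope-threshold detector. The ECG is first high-pass filtered at 10 Hz
(zero-phase, 4th-order Butterworth overall) and the first 50 samples are
zeroed so a recording that opens mid-QRS cannot stall the detector. The
5-point weighted slope $s(n) = -2x(n-2) - x(n-1) + x(n+1) + 2x(n+2)$ is
compared against an adaptive threshold equal to
`slope_filter_parameter/threshold_divisor` (default 4/16) times an
exponentially updated running mean of recent per-beat maximum slopes,
initialized from the first 2 s. Each crossing yields the maximum-amplitude
sample of the following 100 ms (earliest sample on ties), with a 200 ms
refractory period. Because the threshold is a ratio, detection is
invariant under channel gain changes.

**Atrial windowing.** Atrial activity is measured in a 150 ms window
starting 200 ms before each R peak, i.e. $[r - 200\,\mathrm{ms},
r - 50\,\mathrm{ms})$, which excludes the ventricular far field.

**Segmentation and exclusion.** The record is tiled with non-overlapping
10-second segments, anchored so one boundary coincides with the ablation
instant; a beat exactly on a boundary joins the later segment
(deterministic tie-break). A beat is contamination-flagged on a channel if
its window touches the amplifier rail, exceeds 8x the running median of
per-beat peak-to-peak amplitudes in absolute value, or overlaps a declared
saturation interval. Segments with strictly more than 20% contaminated
beats are excluded — a segment with exactly 20% (2 of 10 beats) is
retained, the literal reading of the exclusion rule. Unipolar segments
beginning between ablation and +30 s are always invalid: PFA saturates the
unipolar amplifier for up to 30 s, and the same start is used for all
modalities so the grids are comparable. The saturation rule applies only
to the unipolar channel; bipolar analysis continues from the ablation
instant.

**Sub-band decomposition.** Each 10-s segment is decomposed with a
Daubechies-6 discrete wavelet transform into 9 dyadic detail levels.
Detail level $k$ at sampling rate $f_s$ nominally occupies
$(f_s/2^{k+1}, f_s/2^k]$, so at 1 kHz levels 1–3 jointly span
62.5–500 Hz (the high-frequency preset, capturing the depolarization
spike of bipolar iEGMs) and levels 6–9 span ~0.98–15.6 Hz (the
low-frequency preset, capturing the COI of unipolar iEGMs). The deep
approximation (< ~1 Hz) is excluded from the LF preset because the band
of interest starts at 1 Hz. Band signals are reconstructed by inverting
the transform with all other coefficients zeroed; the per-level
reconstructions plus the approximation sum back to the input exactly.

**Features and normalization.** The feature for a segment is the median
across its clean beats of the peak-to-peak amplitude of the band signal
inside the atrial window. The time grid keeps the last two complete
pre-ablation segments (the two baseline points) and every post-ablation
segment; excluded segments are gaps, never zeros. Two normalization
conventions are used: bipolar HF series are divided by a pre-ablation
reference, unipolar LF series by the first valid post-ablation value
(the 30 s point), making the reference exactly 1 and the series invariant
under channel gain.

On the pre-ablation reference there is a genuine ambiguity: published
descriptions of this normalization convention vary between the *first*
and the *last* pre-ablation value. Both are implemented
(`normalize_series(..., pre_reference =)`); the default is the last
baseline point, the one closest to treatment. With only two baseline
points the choice is numerically minor.

## Statistics

Group comparisons use a linear mixed-effects model on the normalized
series restricted to 30 s–3 min post-ablation:
`value ~ time * group + (1 | animal)`, with time continuous in seconds,
fit by REML (`lmerTest`), and Satterthwaite ANOVA p-values reported for
the time and time-by-group effects. Continuous time is the natural choice
because the scientific claim is about slopes of recovery; REML is the
conventional default for variance estimation with few groups. Singular
fits are flagged, not hidden. Per-timepoint two-group differences use a
data-driven branch: Shapiro-Wilk on each group and a median-centred
Levene test (a specific variance test is not prescribed anywhere; Levene
on medians is the robust standard), both at alpha = 0.05 — both normal
with equal variances gives a pooled t test, anything else Mann-Whitney.
No multiple-testing correction is applied across timepoints;
per-timepoint significance is reported raw. Per-lesion
recovery slopes are ordinary least-squares fits over the valid points of
the same interval.

## Transmurality prediction

The group-level separation at 60 s is made operational as a per-lesion
rule: the score is the normalized unipolar LF value at the valid segment
centre nearest the decision time (default 60 s; ties go to the later
segment), and a score below a threshold — fast COI recovery — is called
nontransmural. A score exactly at the threshold is called transmural,
erring toward the durable-lesion call. The threshold is calibrated by
maximizing Youden's J on labelled training lesions, falling back to the
pooled median when the score distributions are indistinguishable. This
classifier extrapolates beyond the reported evidence, which is
group-level significance rather than a per-lesion decision rule; it is
validated on synthetic cohorts only and makes no claim of clinical
validity. RFA lesions are refused by design: COI recovery showed no
transmurality discrimination after RFA.

## The synthetic generator

The porcine recordings behind these observations are not publicly
deposited, so the generator is a first-class, tested module. Each beat carries:

* on the ECG, a biphasic QRS (1.5 mV) and a small P wave;
* on the bipolar channel, a narrow biphasic spike (derivative-of-Gaussian,
  4 ms total support, 1.5 mV) whose energy lies above 63 Hz;
* on the unipolar channel, a wider biphasic deflection (30 ms, 1 mV)
  followed immediately by a 100 ms raised-cosine COI plateau (3 mV at COI
  level 1) whose energy lies in 1–16 Hz.

Post-ablation, the spike amplitude follows the HF survival trajectory
$h(t) = p - (p - d)\,e^{-t/\tau}$ (immediate drop to $d$, recovery toward
plateau $p$) and the plateau follows the COI trajectory
$c(t) = f + (j - f)\,e^{-(t-30)/\tau}$ (level $j$ at the first valid
reading 30 s post-ablation, decay toward floor $f$). Group defaults
encode the reported dynamics: PFA jump 1.73 (the +73% initial increase),
HF drop to 0.2 for all transmural lesions, recovery to a 0.6 plateau
(time constant 70 s) only for nontransmural PFA, faster COI decay for
nontransmural (tau 45 s) than transmural (150 s) PFA lesions, no initial
COI jump for RFA, and identity dynamics for SHAM (catheter in place, no
energy). Heart rate is 80 bpm with ±3% RR jitter; all channels get
0.05 mV white noise; PFA recordings rail the unipolar channel at +10 mV
from ablation to +30 s; optional movement artifacts add 15 mV
low-frequency transients to randomly chosen beats, recorded in the ground
truth. Cohorts default to the study design — 38 lesions (21 PFA of which
6 nontransmural, 17 RFA of which 9 nontransmural, following the reported
dose-titration outcomes) across 5 animals — with one multiplicative
log-normal amplitude factor (sd 0.2) per animal, giving the mixed model a
true random intercept to recover.

Template geometry was fixed once so the model is internally consistent
with what the pipeline measures: the atrial deflection is centred 160 ms
before the R peak, which keeps the deflection *and* the COI plateau that
follows it inside the $[-200, -50)$ ms window, and the plateau amplitude
(3 mV) dominates the deflection's low-frequency leakage. With that
geometry the normalized HF and LF series of a noise-free lesion track the
generating trajectories within 10% relative error at every valid segment
centre over a full 10-minute course — the key fidelity property the test
suite asserts. What the generator does **not** emulate: real atrial
electrogram morphology and its beat-to-beat variability, fractionated
potentials, far-field ventricular components on the iEGM channels,
respiration and catheter-drift baseline wander, or arrhythmic rhythms.
Passing tests therefore demonstrate that the pipeline measures what it
claims on signals obeying the stated model, not that it is robust to
every artifact of clinical recordings.

## Numerical choices

The wavelet transform is implemented in the package (no suitable wavelet
dependency is available to it): an orthonormal periodized db6 filter bank
applied after extending each analysis block with half-sample mirror
margins to a multiple of $2^9$ samples, then trimming. The mirror margins
give symmetric boundary behaviour at block edges; the periodized core
makes reconstruction exact (relative $L_2$ error below $10^{-8}$, in
practice ~$10^{-15}$) for arbitrary input lengths, including the odd ones.
Per-beat windows of early beats reach up to 200 ms before their segment,
so the decomposed slice is extended left accordingly. Degenerate inputs
are handled explicitly: constant signals decompose into the approximation
alone; flat ECGs yield zero detections; segments with no clean beats are
invalid rather than zero; identical samples in the per-timepoint test
return p = 1; thresholds on empty or one-class label sets are refused.

## Problem sizes

The test suite and the acceptance script run cohorts with 100–200 s of
post-ablation recording and 10–40 lesions — enough to cover the 30 s–3 min
analysis interval and the 60 s decision point with comfortable margins —
and calibrate the mixed-model machinery on 200 table-level replicates
(type-I error of the interaction ANOVA within 5% ± 3 points, power at a
3-residual-SD slope divergence above 80%). Statistical calibration uses a
table-level simulator (`simulate_feature_table`) that draws normalized
values directly from the trajectory functions, because fitting hundreds
of mixed models does not require re-synthesizing 1 kHz signals; the
signal-level generator is exercised end-to-end in the pipeline, QRS,
recovery and classifier tests.

## A short example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  generator = generator_config(duration_post_s = 200),
  cohort = list(n_pfa_trans = 15, n_pfa_nontrans = 6,
                n_rfa_trans = 8, n_rfa_nontrans = 9),
  seed = 1
)
res <- run_pipeline(cfg)
res
autoplot(res, band = "unipolar_LF")
```

## Known limitations

* The wavelet band edges are nominal dyadic edges; db6 filters have finite
  transition bands, so tones near an edge split between adjacent levels
  (a 40 Hz tone lands mostly between the two presets, by design).
* The artifact thresholds that replace visual inspection are validated
  against synthetic ground truth only.
* The transmurality threshold is synthetic-data-calibrated; nothing here
  is a clinical decision rule.
* With five animals, the random-intercept variance is estimated with
  large spread; it is unbiased on average, which is what the tests check.
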