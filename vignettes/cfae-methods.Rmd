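---
title: "Methods: quality-gated nonlinear characterization of fractionated atrial electrograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quality-gated nonlinear characterization of fractionated atrial electrograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Complex fractionated atrial electrograms (CFAEs) are bipolar intracardiac
recordings acquired during atrial fibrillation (AF), characterized by
multiple continuous deflections or short activation cycles (cycle length
at or above 120 ms with isoelectric intervals). They are used to map the
arrhythmogenic atrial substrate, and in particular to discriminate
paroxysmal (ParAF) from persistent (PerAF) AF, which ablate differently.
Two practical issues dominate the reliability of CFAE-based indices:
artifacted or noisy segments (catheter contact loss, baseline drift) bias
the computed indices, and the indices fluctuate strongly both within a
recording and across the recording sites of one patient, so naive
averaging oversimplifies the substrate. The package implements a pipeline
that (i) gates segment quality explicitly and propagates the gating across
analysis window lengths, (ii) computes four substrate indices — sample
entropy (SE), recurrence determinism (DET), AF cycle length (AFCL), and
dominant frequency (DF) — (iii) quantifies index stability with the
coefficient of variation, and (iv) feeds a feature-selected, deliberately
shallow ("coarse") decision tree classifier evaluated with
leave-one-patient-out cross-validation (LOPO-CV).

All analyses assume 16 s single-channel recordings sampled at 1 kHz, one
per recording site (the four pulmonary-vein ostia LSPV, LIPV, RSPV, RIPV
and the anterior/posterior left-atrial free wall ANT, POS), labelled
ParAF or PerAF per patient.

## The synthetic electrogram generator

Clinical CFAE recordings are not distributed with the package; a
generator (`generate_cfae`, `generate_cohort`) stands in for them so that
every downstream stage is testable. It emulates:

* **Quasi-periodic activation** — activation times are a jittered renewal
  process: intervals drawn as Normal(`mean_cl`, `cl_jitter_sd`) and
  truncated below at a 100 ms refractory floor. `mean_cl` must be
  ≥ 120 ms, consistent with the CFAE definition.
* **Fractionated complexes** — each activation is a sum of
  `fractionation` biphasic deflections (derivative-of-Gaussian wavelets of
  width `deflection_width` ms), one at the activation time and the rest
  offset within ±25 ms with random amplitude (0.4–0.9 of the main
  deflection) and polarity. The sub-deflection layout is drawn **once per
  recording** and repeated at every activation: a recording site has a
  stable local substrate geometry, and this repeatability is precisely
  what makes organized electrograms deterministic in the recurrence-plot
  sense. Class differences therefore come from cycle length, jitter, and
  fractionation, not from per-beat shape churn.
* **Noise and interference** — the activation component is normalized to a
  1 mV peak (the amplitude distribution of clinical CFAEs is not pinned
  down, so a normalized scale is used); white baseline noise of SD
  `noise_sd` and a powerline tone of amplitude `powerline_amp` are added.
* **Artifacts** — `inject_artifacts` adds the two artifact classes the
  quality stage screens for: low-frequency drift (an additive sub-2 Hz
  half-sine of several mV) and signal loss (amplitude multiplied by 0.01 —
  near zero, but not exactly zero, so near-zero-range thresholds are
  genuinely exercised). `generate_cohort` schedules one such artifact in
  half of the recordings (one or two whole seconds at a random position),
  which puts the per-segment discard rate in the single-digit-percent
  range reported for clinical electrograms.

The class presets (`af_preset`) are: ParAF `mean_cl` 185 ms, jitter SD
10 ms, fractionation 2; PerAF `mean_cl` 145 ms, jitter SD 25 ms,
fractionation 5; both with `noise_sd` 0.01 mV and `powerline_amp`
0.05 mV. They were chosen once so that the synthetic class contrasts run
in the clinically reported directions — higher SE, lower DET, shorter
AFCL, higher DF in persistent AF — and the test suite verifies those
directions across seeds. Two calibration notes: at noise SD ≈ 0.02 mV and
above, the white-noise floor starts to dominate template matching and the
SE contrast degrades, which is why the preset sits at 0.01 mV (1% of
peak); index *magnitudes* are emphatically not calibrated to any clinical
cohort. Cohorts draw patient-level parameters around the preset (cycle
length ± 8 ms SD, jitter ± 3 ms SD, fractionation ± 1) and per-site
perturbations of the cycle length (± 4 ms SD), so sites of one patient are
similar but not identical.

**What the generator does not emulate:** no biophysical (ionic or
monodomain) tissue model, no ventricular far-field deflections, no
spatial correlation between sites beyond shared patient parameters, no
electrode-motion morphology changes, and noise is white rather than the
colored mixture of real laboratories. Passing tests on synthetic cohorts
therefore demonstrate the *pipeline's* correctness and the *direction* of
preset-driven contrasts, not clinical effect sizes.

## Preprocessing

**Powerline cancellation.** Interference is removed by detected harmonic
regression (`remove_powerline`): for the mains frequency (50 or 60 Hz)
and its first harmonic, the raw periodogram line is compared with the
median periodogram in a ±10 Hz neighbourhood (central ±1 Hz excluded);
when the line exceeds 10× the background, the signal is least-squares
regressed on a sine/cosine pair at that frequency over the full 16 s and
the fitted component subtracted. Design rationale: a stationary tone is
removed exactly and with zero phase distortion, only a 1/16 Hz-wide line
is ever taken from the signal, and — because of the detection step — an
interference-free electrogram passes through bit-identically. A zero-phase
IIR notch was evaluated first and rejected: with a quality factor sharp
enough to spare the signal, its forward-backward transients (the notch
passes DC, and reflection padding of an arbitrary-phase tone leaves a DC
pedestal step at the junction) contaminated hundreds of milliseconds at
the record edges. The detection step also matters statistically:
quasi-periodic electrograms carry a few tenths of a percent of genuinely
coherent energy at any fixed frequency, and subtracting it
unconditionally measurably distorts clean signals.

**Botteron-style envelope.** `botteron_transform` band-pass filters to
20–250 Hz, rectifies, low-pass filters at 20 Hz, and clips at zero; all
filters are 2nd-order Butterworth applied forward-backward (4th-order
zero-phase), so activation times are not biased. The low band edge is
20 Hz — lowered from the classical 40 Hz — to favour slow local
activations; the upper edge is the classical 250 Hz (the modified
approach leaves it unstated).

**Amplitude equalization.** `equalize_activations` divides the envelope
by a running 95th-percentile estimate over a **0.2 s** window, floored at
5% of the global 95th percentile. The window length is deliberately
shorter than one activation cycle: it covers a single complex but, at
cycle lengths ≥ 120 ms, not its neighbours, so consecutive activations of
very different amplitude are normalized toward a common height (verified:
alternating 10:1 peaks equalize to within a factor of 2). A multi-second
window cannot achieve this — both peak families fall into every window and
the running percentile is nearly constant — which is why the short window
was adopted. The floor prevents isoelectric noise from being amplified
without bound.

## Quality gating

The 1 s segments of each recording are screened automatically
(`build_q1`) for the two artifact classes:

* **Low-frequency drift** (`lowfreq_artifact_flag`): flagged when the
  Welch screening spectrum (256-sample Hamming sections, 50% overlap,
  zero-padded to a 1024-point FFT — the padding buys sub-hertz bins that a
  256-point FFT at 1 kHz does not have) peaks higher in (0, 2] Hz than
  `lf_peak_ratio` (default 1) times its 3–12 Hz peak, **and** the segment
  peak exceeds `amp_factor` (default 2) times the recording's median
  per-second peak. The amplitude conjunct encodes "abnormal amplitude
  and/or shape": drifts that do not distort amplitude are left alone.
* **Signal loss** (`signal_loss_flag`): flagged when the segment range is
  strictly below 10% of the recording's median per-second range (or an
  absolute `loss_range_mv`).

The screen replaces a visual, clinician-adjudicated assessment; a manual
override vector (same serialized format as the automated vectors,
`read_quality_vectors`) substitutes wholesale when supplied. Bits are
1-based and 1 = acceptable. Coarser vectors are products of consecutive
disjoint blocks (`propagate_quality`), preserving time correspondence: a
2 s or 4 s segment is acceptable only if every second inside it is. This
makes the discarded fraction provably nondecreasing in the window length,
and `discard_summary` also reports the embedded information loss — good
seconds censored because they share a coarse segment with a bad one.

## Substrate indices

**Sample entropy.** `SE(m, r, N) = −ln(A/B)`, where `B` and `A` count
template pairs of length `m = 2` and `m + 1` matching within
`r = 0.35 × SD(segment)` under the Chebyshev (maximum absolute
coordinate) distance, self-matches excluded, both template lengths taken
over the same `N − m` starting points. Degenerate segments (zero SD; no
`(m+1)`-matches) return flagged `NA` and are treated as discarded rather
than clamped. SE is invariant to offset and positive scaling because `r`
scales with the SD.

**Embedding selection.** The delay is the first minimum of the
auto mutual information (16 equiprobable bins); because the histogram
estimate wiggles at the single-lag scale, a minimum must hold over a
±3-lag neighbourhood. The dimension comes from false nearest neighbours
with both classical criteria OR'd: distance-ratio `Rtol = 10` and
attractor-size `Atol = 2` (without the latter, the FNN fraction of pure
noise drifts under 1% at moderate dimensions through distance
concentration, and noise would not saturate at `max_d`). Two numerical
safeguards: the ratio denominator is floored at `1e-3 ×` SD, so
near-coincident returns of noiseless periodic orbits are not declared
false by 0/0-type ratios, and the all-pairs search uses at most the first
1000 embedded points of a segment (contiguous truncation, which preserves
the dynamics, unlike subsampling). Per window length, one global
embedding is adopted: the mode of the per-segment dimension and delay
votes, ties broken toward the smaller value.

**Recurrence determinism.** `R(i,j) = Θ(ε − ‖x_i − x_j‖)` over the delay
embedding; DET is the fraction of recurrence points on diagonals of at
least `lmin = 50` points, with the line of identity excluded from both
counts (Theiler window of one — `lmin` is read in recurrence points, the
only unit-free reading). The threshold is `ε = 0.10 ×` the phase-space
**diameter** (maximum pairwise distance among embedded points;
`eps_mode = "diameter"`). The mean-pairwise-distance alternative is
available (`eps_mode = "mean_dist"`) but is not the default: with
realistic additive noise the mean distance of an
isoelectric-interval-dominated electrogram sits at the noise-cloud scale,
recurrences become noise-limited, and DET degenerates toward zero at
every embedding — incompatible with the 0.5–0.7 determinism that
organized electrograms exhibit. With the diameter rule, synthetic ParAF
recordings land in that range and PerAF clearly below it. The pipeline's
`rqa_determinism` streams the diagonal scan without materializing the
N × N matrix (a 4 s segment embeds ~4000 points); `recurrence_matrix` +
`determinism` expose the explicit-matrix path, and the two are tested for
exact equality.

**Cycle length and dominant frequency.** Activations are detected on the
equalized envelope as local maxima above 0.3 × a running 95th percentile
(2 s window), thinned by a 100 ms refractory rule (strongest peak wins);
AFCL is the mean inter-activation interval over the full 16 s. DF is the
largest Welch-spectrum peak in 3–12 Hz (Hamming window of 4096 points,
50% overlap, 8192-point FFT; resolution 1000/8192 ≈ 0.122 Hz), computed
on the **Botteron envelope** rather than the raw electrogram: the raw
deflections are a few milliseconds wide, so their spectral envelope peaks
far above the fibrillatory band and a high harmonic of the activation
rate can outweigh the fundamental inside 3–12 Hz; on the smooth envelope
the fundamental dominates and DF ≈ 1000/AFCL on clean periodic trains
(the suite asserts agreement within 0.3 Hz). Both indices are computed on
the full recording regardless of the quality vector by default; passing
`q1` to `rate_indices` masks discarded seconds instead (activations
inside them dropped, intervals spanning them excluded, envelope zeroed
for the spectrum).

## Stability and testing battery

The coefficient of variation is `100 × sd/|mean|` with the sample (n−1)
SD — per-recording segment counts are small, so the unbiased-variance
convention matters. Intra-recording CV is computed across the segments of
each recording and averaged over recordings with equal weight (pooling is
the other defensible reading; equal weighting was chosen so that long
runs of segments from one noisy recording cannot dominate); recordings
with fewer than two usable segments are skipped and listed.
Intra-patient CV first averages each site, then takes the CV across site
means per patient, then averages patients. Both are reported with and
without discards and as the relative change ΔCV.

Kruskal–Wallis (via `stats::kruskal.test`, tie-corrected) asks, per
patient, whether an index is homogeneous across sites; results are
flagged unreliable when any site contributes fewer than five values,
where the chi-square reference degrades. Homoscedasticity is checked with
the Breusch–Pagan auxiliary regression (LM = n·R² of squared residuals on
group indicators, chi-square with groups − 1 df; equivalent to the
studentized form, and cross-checked against an independent implementation
in the tests). The ParAF/PerAF comparison per site and index is a
two-sided Mann–Whitney test on per-recording summaries (mean over usable
segments; segment-level pooling available via `pool_segments`), and the
three window-length p-values are arithmetically averaged. That averaging
is a *reporting convention*, not a combined inference — the three
datasets are derived from the same recordings and the average of p-values
has no sampling-theory justification; the per-window p-values are
therefore always reported alongside. No multiple-testing correction is
applied by default; `p_adjust = "holm"` adds a Holm-adjusted column.

## Feature selection and classification

The feature matrix has one row per patient and 24 columns — {SE, DET,
AFCL, DF} × six sites — with SE/DET summarized per recording as the mean
over usable segments of the chosen window length, AFCL/DF from the 16 s
computation, and the label TYPE coded 0 = ParAF, 1 = PerAF. Missing cells
stay `NA` (never imputed); rows with missing features are dropped from
the forest with a warning.

The redundancy filter works on the element-wise **average** of the three
window-length correlation matrices: while any pair exceeds |r| > 0.60,
the member of the worst pair with the larger mean absolute correlation to
the remaining features is dropped (ties by column order). The rule is
deterministic, row-order invariant, and scale invariant. Relevance comes
from a seeded 500-tree Random Forest with stratified bootstrap
(per-class sample sizes fixed at the class counts); mean-decrease-Gini
importances are rescaled so the maximum is 100 and features scoring
above 40 are selected. The "coarse tree" is a Gini decision tree pruned
back to at most 4 splits (grown with `rpart` at `cp = 0`, then cut at the
largest complexity-table entry with ≤ 4 splits), the established meaning
of that model class in clinical classification toolboxes. All 2^k − 1
subsets of the ≤ 12 selected features are evaluated by LOPO-CV (every row
of the held-out patient removed from training); ties in accuracy go to
the smaller subset, then column order, so the minimal winning feature set
is reported. Single-feature coarse-tree accuracies are always computed on
the full, unfiltered 24 features: the redundancy filter exists to shrink
the multi-feature search, and applying it to one-input models would
merely hide individually informative indices.

## Numerical choices and problem sizes

* Zero-phase filtering pads by odd reflection (2000 samples) before
  `signal::filtfilt` and trims, so Butterworth transients stay out of the
  retained record.
* Running percentiles are evaluated on a hop grid (window/4) and linearly
  interpolated — amplitude tracking does not need exact sliding
  quantiles.
* The C++ kernels (sample-entropy counts, recurrence/DET scan, FNN) work
  in the squared-distance domain with early exits; the recurrence scan
  covers the upper triangle only, which leaves the DET ratio of a
  symmetric matrix unchanged.
* Every fast path has a brute-force oracle in the test suite (double-loop
  template counts, explicit histogram MI, full-matrix FNN, all-pairs
  recurrence matrices, diagonal-run counters, section-by-section Welch),
  asserted for exact equality on seeded fixtures.
* Test-suite problem sizes were chosen for a single-CPU workflow: oracle
  fixtures at N ≤ 300 (recurrence matrices at 30 points), directional
  class contrasts over 20 seeds with one pooled embedding, a null
  calibration of the rank-sum stage over 1000 synthetic cohorts, and an
  end-to-end smoke cohort of 4 + 4 patients × 6 sites across all three
  window lengths. `run_config(embedding_segments = 48)` bounds how many
  segments are polled for the global embedding; increase it for
  production-size cohorts.
* Determinism: a single `seed` drives cohort synthesis, the forest, and
  every derived stage seed (all below 2^31); a fixed seed reproduces the
  report bundle bit for bit, and each output table carries a hash of the
  generating configuration.

## Known limitations

* The quality screen implements exactly two artifact classes; electrode
  motion, ventricular far field, and saturation artifacts are out of
  scope (a manual override file is the escape hatch).
* DET is sensitive to the selected delay: periodic signals embedded far
  from the quarter-period delay score lower, and the global-mode
  embedding can sit away from any individual segment's optimum. This
  mirrors the method being reproduced (one embedding per window-length
  dataset) rather than a per-segment optimum.
* The averaged-p-value convention and the absence of multiplicity
  correction are inherited reporting choices; treat the test battery as
  descriptive.
* Synthetic cohorts cannot validate clinical effect sizes — only
  pipeline correctness, calibration under the null, and the direction of
  preset-driven contrasts.
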