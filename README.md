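# cfae — quality-gated nonlinear characterization of fractionated atrial electrograms

Complex fractionated atrial electrograms (CFAEs) — bipolar intracardiac
signals with multiple continuous deflections or short-cycle activity — are
widely used to map the arrhythmogenic substrate in atrial fibrillation
(AF). Two practical problems undermine CFAE-based substrate assessment:
noisy or artifacted segments bias the indices computed from them, and the
indices vary so much within a recording and between recording sites that
averaging can wash out the substrate's spatial structure.

`cfae` is an R package for electrophysiology signal analysts that
implements a complete, reproducible pipeline around those two problems:

* **Synthetic electrogram generator** — quasi-periodic fractionated
  activations (cycle length ≥ 120 ms with beat-to-beat jitter), stable
  per-site complex morphology, baseline noise, powerline interference, and
  two scheduled artifact classes (low-frequency drift; signal-loss
  intervals), with paroxysmal (ParAF) and persistent (PerAF) presets and
  full ground-truth annotations.
* **Preprocessing** — powerline cancellation by detected harmonic
  regression, and the Botteron-style transform (band-pass 20–250 Hz,
  rectify, low-pass 20 Hz) with amplitude equalization for activation
  detection.
* **Quality gating** — automated per-second screening for the two artifact
  classes, the binary quality vector `q_w` per window length
  `w ∈ {1, 2, 4}` s, product propagation `q_w(j) = Π q_1((j−1)w+1 … jw)`,
  and discard/information-loss bookkeeping.
* **Substrate indices** — sample entropy
  `SE(m, r, N) = −ln [B_{m+1}(r) / B_m(r)]` with `m = 2`,
  `r = 0.35·SD`; recurrence-plot determinism (fraction of recurrence
  points on diagonals of length ≥ 50, embedding chosen by mutual
  information and false nearest neighbours, ε = 10% of the phase-space
  diameter); AF cycle length (mean interval between detected activations);
  and dominant frequency (largest Welch-spectrum peak in 3–12 Hz; Hamming
  4096, 50% overlap, 8192-point FFT).
* **Stability assessment** — intra-recording and intra-patient coefficient
  of variation (CV = σ/μ, %) with and without discards, plus
  Kruskal–Wallis, Breusch–Pagan, and Mann–Whitney testing.
* **Classification** — patients × (index, site) feature matrix,
  correlation-filter redundancy removal (cutoff 0.60), Random-Forest Gini
  ranking (scores 0–100, selection > 40), and exhaustive coarse-tree
  (≤ 4 splits) subset search with leave-one-patient-out cross-validation.

## Worked example

A single synthetic persistent-AF recording, cleaned and characterized:

```r
library(cfae)

rec   <- generate_cfae(af_preset("PerAF", seed = 42))
clean <- remove_powerline(rec)
segs  <- segment_signal(clean, w = 1)
emb   <- select_global_embedding(segs)
se    <- mean(sapply(segs, sample_entropy), na.rm = TRUE)
det   <- mean(sapply(segs, function(s) rqa_determinism(s, emb)$det))
rate  <- rate_indices(clean)
cat(sprintf("SE = %.3f  DET = %.3f  AFCL = %.1f ms  DF = %.2f Hz\n",
            se, det, rate$afcl_ms, rate$df_hz))
cat(sprintf("embedding: d = %d, tau = %d samples\n", emb$d, emb$tau))
```

```
SE = 0.036  DET = 0.065  AFCL = 147.0 ms  DF = 6.71 Hz
embedding: d = 8, tau = 18 samples
```

The PerAF preset is short-cycled (AFCL ≈ 147 ms, DF ≈ 6.7 Hz ≈
1000/AFCL) and weakly deterministic, as expected for a disorganized
substrate. A full cohort run — synthesis, quality gating, indices,
stability, selection, classification (a minute or two on one CPU for
4 + 4 patients):

```r
bundle <- run_pipeline(run_config(n_par = 4, n_per = 4, seed = 11))
subset(bundle$discards, group_type == "all")
subset(bundle$stability, level == "intra_recording" & scope == "all" &
         index == "SE")
aggregate(cbind(AFCL, DF) ~ af_type, bundle$rec_tab, mean)
```

```
  group_type group w discard_pct info_loss_pct
1        all   all 1    3.125000      0.000000
2        all   all 2    5.468750      2.343750
3        all   all 4    9.895833      6.770833

            level index w scope cv_nodiscard cv_discard delta_cv_pct
1 intra_recording    SE 1   all     33.52814   9.248082    -72.41696
4 intra_recording    SE 2   all     24.49541   5.423652    -77.85850
7 intra_recording    SE 4   all     15.67470   3.038059    -80.61807

  af_type     AFCL       DF
1   ParAF 182.2125 5.457560
2   PerAF 138.3448 7.319132
```

Discards grow with the window length (a bad second censors the whole
coarse segment it sits in), removing them sharply stabilizes the
intra-recording CV — more so for longer segments — and the class contrasts
run in the expected directions (shorter cycle length and higher dominant
frequency in persistent AF). With `out_dir` set, every table is written as
CSV together with a `run.log`; `inst/scripts/run_pipeline.R` wraps the
same call for shell use.

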