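---
title: "Methods: EEG-based trust evaluation, from raw signal to classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG-based trust evaluation, from raw signal to classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trusteeg)
```

`trusteeg` turns a mentor surgeon's intraoperative EEG into a binary judgement
about a trainee: *trustworthy* or *concerning*. This vignette is the package's
account of how that works — the model and its assumptions, every tunable
parameter that matters, the numerical conventions, and what the synthetic
experiments can and cannot establish.

## 1. Signal model and preprocessing

A recording is a channels × time matrix (native amplitude units, 256 Hz by
default) over the 20-electrode montage, partitioned into six cognitive
systems (frontal, prefrontal, central, temporal, parietal, occipital). The
pipeline assumes stationarity only at the 1-second window scale, and treats
artifacts as contamination to be *masked*, never interpolated into the stored
signal: masks drive all downstream exclusion, and sample values are never
altered by a detector.

Preprocessing parameters (all configurable, defaults in parentheses):

| parameter | default | role |
|---|---|---|
| `spike_threshold` | 40 (native units) | absolute amplitude defining saturation/excursion runs |
| spike run lengths | 3, 5, 7 samples | run lengths flagged as spikes |
| `notch_hz` | 60 Hz | mains interference |
| broad band-pass | 0.5–128 Hz | analysis band |
| `blink_k` | 6 × MAD | frontal 0.5–4 Hz deflection threshold |
| blink minimum duration | 50 ms | rejects single-sample crossings |
| `window_sec`, `overlap_frac` | 1 s, 0.5 | spectrogram resolution |
| Kaiser β | 8.6 | taper sidelobes (Blackman-like) |
| window rejection | > 25% masked | drops a spectral window |
| outlier rule | 3 SD, single pass | per-channel series cleaning |

Conventions worth stating explicitly:

- **Long excursions.** Supra-threshold runs *longer* than 7 samples are also
  masked (a superset rule): a long saturation is at least as contaminated as a
  short spike. Turn off with `mask_long_runs = FALSE`.
- **Blink detection** is a deliberately simple threshold detector — a frontal
  0.5–4 Hz deflection exceeding 6 MADs for ≥ 50 ms. Classifier-based blink
  detectors need training corpora; the threshold rule is fully transparent and
  its recall is verified against injected ground-truth templates. The blink
  mask of a frontal channel is shared across channels, since a blink
  contaminates the instant, not one electrode.
- **Filter order and phase.** All filters are Butterworth applied
  forward–backward (zero phase), because the connectivity stage estimates
  instantaneous phase and a causal filter would bias it. The notch is applied
  before the broad band-pass; both are linear, so the order only matters at
  the edges and is fixed for reproducibility. When the upper band edge reaches
  Nyquist (0.5–128 Hz at 256 Hz sampling) the band-pass degenerates to the
  corresponding high-pass.
- **Spectral windows** with > 25% masked samples are dropped; in retained
  windows masked samples are linearly interpolated *for the FFT only*. The
  window count, not the data, absorbs contamination.
- **Outlier removal is single-pass** by convention: mean and SD are computed
  once on the full series. Iterating the rule would remove more points (the
  tests demonstrate this on a constructed series); the single pass is the
  documented, idempotence-breaking choice, so it is applied exactly once per
  series.
- **Units.** The 40-unit spike threshold is kept in the recording's native
  units and is configurable: scalp EEG is physiologically microvolt-scale, so
  the right threshold depends on the acquisition chain's scaling.

## 2. Cognitive features

Five closed-form features are computed per recording; two more (mental
workload MW, engagement E) are *pass-through slots* for externally supplied
probabilities because they come from proprietary baseline-calibrated
classifiers that this package does not reproduce.

- **Mental load** `ML_i = Σ_{j∈i} A(j)`. "Total power amplitude" is given a
  precise meaning: `A(j)` is the channel's integrated PSD over the full
  analysis band, averaged over retained windows, and `ML` is its sum over the
  system's channels. Power (not amplitude, i.e. not the square root) was
  chosen: it makes `ML` additive over disjoint frequency bands and linear in
  PSD scaling, at the cost of quadratic sensitivity to gain.
- **Situation awareness** `SA = PSD^F(θ) + PSD^F(γ)`: absolute (not relative)
  band-integrated power, averaged over frontal channels then over windows.
  Absolute power keeps `SA` linear; a relative variant would entangle it with
  broadband power changes.
- **Blink rate** `BR = N_c / N`: the fraction of time points blink-masked on
  any channel.
- **Asymmetry index** `AI = (L − R)/(L + R)`, where `L` (respectively `R`)
  sums the dynamic range (max − min over windows) of alpha-band power at
  F3 and F7 (F4 and F8). Raw extrema are artifact magnets, so the per-window
  alpha series is cleaned with the single-pass 3-SD rule before the range is
  taken. A completely flat input makes the ratio 0/0 and raises an error
  rather than returning a silent 0.
- **Completion time** `CT = N / f_s`.

Invariances the tests enforce: scaling all PSD values by `c > 0` scales ML
and SA by `c` and leaves AI fixed; swapping left and right frontal channels
flips AI's sign; BR ignores amplitude entirely.

## 3. Phase-locking connectivity

Per band, each channel is band-pass filtered (zero-phase) and its analytic
signal computed by FFT; the instantaneous phase is the analytic argument,
wrapped to (−π, π]. This is the standard phase-locking-value construction.
An empirical-mode or wavelet decomposition could substitute, but cannot
assign modes to fixed frequency bands deterministically, which the band-wise
feature definitions require.

For a channel pair, the synchronization index is the resultant length

```
Γ_xy = √((Σ_t cos Δφ)² + (Σ_t sin Δφ)²) / P .
```

Conventions:

- Γ is evaluated on the **signed** wrapped phase difference. Cosine is even,
  so this equals the same formula on the unnormalized difference; the folded
  absolute difference in [0, π] returned by `phase_difference()` is a
  reporting convention. (Folding *before* the sine sum would floor the
  independent-channel null at 2/π ≈ 0.64 — the signed form recovers the
  correct 1/√P-scale null.)
- A time point is excluded for a pair if masked on *either* channel; `P` is
  the per-pair retained count, recorded in the matrix object.
- The diagonal is 1 by definition.
- One Γ is computed over the full recording rather than averaging window-wise
  estimates; the single normalization by `P` presumes exactly that, and a
  full-recording resultant is the stricter notion of sustained locking.
- **Strength** (within-system mean) excludes self-pairs: including the unit
  diagonal would floor every two-channel system (prefrontal, occipital) at
  0.5 and compress real differences. **Communication** between systems is
  the plain cross-block mean, `Σ Γ_ij / (|S_k1||S_k2|)`.

Correctness is anchored two ways: Γ is checked against an independent
two-line summation oracle to 10⁻¹² on a thousand random series, and the
whole pipeline (generate → filter → phase → Γ) must recover a known coupling
parameter monotonically (Section 6).

## 4. Labels

The NASA-TLX performance score PS (0–20 tick scale, low = good) gives the
performance level `PL = 20 − PS`, and `PL > 11` — strictly — labels a
recording trustworthy. The 0–20 scale is the only one on which `20 − PS`
is meaningful; the 0–100 TLX variant is rejected by construction. The
mentor's mental-demand score is carried through as the task-complexity
covariate for the complexity-classification contrast.

## 5. Feature ranking and classification

**Kernel-target alignment.** For z-scored features and centered ±1 labels,
the centered alignment of the weighted linear kernel `K(w) = Σ_f w_f x_f x_fᵀ`
with the label kernel reduces to
`A(w) = (a·w) / (√(wᵀMw) ‖y_c‖²)` with `a_f = (x_f·y_c)²` and
`M_fg = (x_f·x_g)²`. The package maximizes `A` by projected gradient ascent
under `w ≥ 0`, `‖w‖₂ = 1`:

- initialization: uniform weights with a small seeded jitter;
- backtracking line search (step halving, up to 40 times) guarantees the
  alignment is non-decreasing across accepted iterations — an invariant the
  tests assert on the stored trace;
- convergence at alignment improvement < 10⁻⁶ or 500 iterations;
- constant (zero-variance) columns are pinned to weight 0 and never selected.

Perfectly correlated features span a flat ridge of `A` (only their combined
weight is identified), so redundant duplicates are handled at the *set*
level: one of the pair heads the ranking, mirroring selectors that keep one
of two correlated features.

**SVM evaluation.** Linear SVM with C = 1 (no tuning grid: the synthetic
and clinical regimes are low-dimensional and near-separable, where C barely
matters). Features are z-scored *inside each training fold*; constant-in-fold
columns are centered only. LOOCV holds out one full recording's feature
vector at a time and is deterministic given the data; 10-fold CV is
stratified by label (with 24 concerning samples, unstratified folds can lose
a class — if a training split still does, the folds are rebuilt with a new
seed and a message). The F-score is F1 on the trustworthy class.

**Dimension sweep.** For d = 2 … `max_dim`, score the top-d KTA features;
the optimum is the *smallest* d attaining the maximum accuracy. Ranking can
run once on the full table (`selection = "outside"`, the default and the
cheaper, reporting-oriented convention) or inside every training fold
(`selection = "inside"`, which removes selection bias); the mode is recorded
in the result so a report is always explicit about it.

**Cluster validation.** Fuzzy C-means (fuzzifier m = 2, up to 300
iterations, seeded initialization) on z-scored features; hard assignments by
maximal membership; cluster-to-label matching by the better of the two
permutations. The separability criterion `J = tr(S_W⁻¹ S_B)` is computed
from the hard assignment on the *raw* feature values (z-scoring first would
cancel the very scale differences J measures). A singular within-scatter is
ridge-regularized with a message.

**Group statistics.** Welch t-tests (the groups are unequal in size and
variance), Bonferroni-corrected across the tested set, flagged at the
corrected 10⁻⁴ / 10⁻³ tiers; Pearson correlations reported at the 95%
confidence level; PCA on z-scored features for visualization, with a zeroed
second component (and a message) on rank-1 input.

## 6. The synthetic-data generators

Clinical intraoperative EEG cannot be redistributed, so the package ships
two generators that stand in for it at the two levels the pipeline needs.

**Feature level.** `uva_group_spec()` and `lnd_group_spec()` encode the
published per-group summaries of the discriminative features for the simple
task (urethrovesical anastomosis: 63 trustworthy / 24 concerning recordings;
three γ-band functional features) and the complex task (lymph node
dissection: 43/40; seven γ-band functional features plus blink rate and
asymmetry index). SDs are recovered from standard errors as SD = SE·√N; a
printed SE of 0.00 is floored at 0.005 (half the last reported digit) to
keep every SD positive. All non-listed features draw from identical group
distributions at field-plausible scales (functional features 0.5 ± 0.1,
mental loads 50 ± 10 power units, SA 20 ± 5, CT 1800 ± 300 s, MW/E centered
probabilities), so only the listed features carry class information.
`sim_feature_dataset()` draws independent Gaussians per feature and clips
to legal ranges ([0,1] for functional features and rates, [−1,1] for AI,
non-negative for power and time); an optional correlation matrix induces
dependence for correlation-analysis tests, because only pairwise r values —
not a covariance — are published.

**Signal level.** `sim_coupled_eeg()` sums, per channel, four band-centre
oscillators whose phase deviation is a convex mixture — weight `g` toward a
shared stationary wander, weight `1 − g` toward the channel's own — plus
white noise. The wander is an Ornstein–Uhlenbeck process (SD 2.2 rad,
relaxation ≈ 1 s, generated at 8 Hz and interpolated, keeping the
instantaneous-frequency perturbation inside a band). The design makes the
pair's phase-difference SD equal `(1−g)√2·σ`, so the estimated Γ rises
smoothly and strictly with `g`: ≈ 0.06–0.1 at `g = 0` (the estimation floor
of a 60 s recording), ≈ 0.97 at `g = 1` with noise, > 0.99 without. An
unbounded random-walk wander was rejected: it saturates decorrelation and
flattens the low-`g` response, breaking monotone recovery.
`inject_artifacts()` adds raised-cosine frontal blink templates and 3/5/7-
sample spike runs at non-overlapping seeded positions and returns the
ground-truth intervals, making detector recall measurable by construction.

**What the generators do *not* emulate** — and therefore what passing tests
do not show about clinical data: 1/f background spectra, volume conduction
and reference effects, non-stationary drift over a 30-minute case, and —
critically — the real covariance *between* features. Independent Gaussian
features at the published effect sizes (per-feature Cohen's d ≈ 3–4 for the
functional features) are *more* separable than correlated real features:
the synthetic classification accuracies are upper-bound analogs, and the
dimension sweep on such data saturates after two or three features, where
the clinical analyses reported needing three (simple task) and nine
(complex task). The sweep machinery is exercised and verified on synthetic
data; the reported clinical optima are properties of the real covariance
structure, which no independent-feature generator can reproduce. Similarly,
the asymmetry index's published group gap is only ≈ 3.6 standard errors, so
on regenerated cohorts it clears an uncorrected 0.05 reliably but a
Bonferroni-corrected threshold only at the ~0.8 power that gap affords —
the tests assert exactly that calibrated behaviour.

## 7. Problem sizes and determinism

The test suite and the acceptance script run entirely on generated data at
the study's own scales: feature-level cohorts of 87 and 83 recordings,
signal-level recordings of 8–60 s at 256 Hz (a full 30-minute recording is
nothing but a longer loop over identical windows, so short recordings
exercise every code path). Classification figures are averaged over ten
regenerated cohorts. Every stochastic step — generation, fold assignment,
KTA initialization, C-means initialization — is seeded explicitly, and
generator output is a pure function of (spec, seed).

## 8. Known limitations

- Blink detection is a threshold rule; heavily artifacted channels with
  non-blink low-frequency power will inflate BR.
- MW and E are accepted, never computed; analyses that include them depend
  on an external classifier's calibration.
- Phase extraction assumes the band-passed signal is narrowband enough for
  the analytic phase to be meaningful; the broad β band (12–35 Hz) stretches
  this assumption most.
- Γ is undirected and volume-conduction-naive: zero-lag spread inflates
  short-range locking on real scalp data.
- The KTA objective is optimized under a non-negativity constraint by
  projected ascent; it is not guaranteed to find the global optimum, only a
  monotone ascent path from its seeded start (in practice the exhaustive
  small-scale comparison in the tests shows the selected subsets are within
  two accuracy points of the best subset of equal size).
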