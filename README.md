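# trusteeg

EEG-based evaluation of mentor–trainee trust in robot-assisted surgery.

During robot-assisted surgery a mentor surgeon continuously judges whether a
trainee's performance can be trusted. `trusteeg` implements a pipeline that
makes that judgement objective from the *mentor's* scalp EEG: it cleans
multichannel recordings, extracts cognitive and functional brain-state
features, and classifies each recording as **trustworthy** or **concerning**
against labels derived from NASA-TLX performance scores. It is aimed at
neuroergonomics and surgical-data-science researchers who want a tested,
reproducible implementation of the method — including a synthetic-data module,
since clinical intraoperative EEG is rarely shareable.

## The model

A recording is a 20-channel scalp EEG (256 Hz) grouped into six cognitive
systems: frontal (F), prefrontal (PF), central (C), temporal (T), parietal
(Pa), occipital (O). From each recording the pipeline computes a 96-dimensional
feature vector:

- **12 cognitive features.** Per-system mental load `ML_i = Σ_{j∈i} A(j)`
  (A(j): the channel's time-averaged integrated power); situation awareness
  `SA = PSD^F(θ) + PSD^F(γ)`; blink rate `BR = N_c / N`; frontal alpha
  asymmetry `AI = (L − R)/(L + R)` with `L` and `R` the α-power dynamic ranges
  of F3+F7 and F4+F8; completion time `CT = N / f_s`; plus pass-through slots
  for externally supplied mental workload (MW) and engagement (E)
  probabilities.
- **84 functional features.** Per band (θ 4–8, α 8–12, β 12–35, γ 35–60 Hz),
  the phase-locking value of every channel pair,
  `Γ_xy = √((Σ_t cos Δφ_xy)² + (Σ_t sin Δφ_xy)²) / P`,
  aggregated into 6 within-system *strengths* and 15 between-system
  *communications* — 21 features × 4 bands.

Labels come from the mentor's NASA-TLX performance score PS via the
performance level `PL = 20 − PS`; a recording is trustworthy iff `PL > 11`.
Features are ranked by kernel-target alignment (KTA): non-negative per-feature
weights of a weighted linear kernel are optimized by projected gradient ascent
to maximize centered alignment with the label kernel. A linear SVM (C = 1,
fold-internal z-scoring) is scored under leave-one-out and stratified 10-fold
cross-validation, and the class structure is validated with fuzzy C-means
clustering and the scatter criterion `J = tr(S_W⁻¹ S_B)`.

## Worked example

```r
library(trusteeg)

# simulate an 87-recording feature table for the simple surgical task
uva <- uva_group_spec()           # published group means/SEs, 63 + 24
d   <- sim_feature_dataset(uva, seed = 42)

ranking <- kta_rank_features(d, n_select = 3, seed = 42)
head(tidy(ranking), 3)
#>   feature    weight  rank selected
#> 1 gamma:F    0.730      1 TRUE
#> 2 gamma:F-C  0.667      2 TRUE
#> 3 gamma:F-Pa 0.0797     3 TRUE

ev <- evaluate_svm(d, ranking$selected, cv = "loocv")
glance(ev)
#>   accuracy f_score cv_scheme n_features     n
#> 1     98.9    99.2 LOOCV              3    87

fuzzy_cmeans_validate(d, ranking$selected, seed = 42)
#> <cluster_report> accuracy 97.70%, J = 4.976

group_ttest(d, ranking$selected)
#>   feature    mean_1 mean_2     t        p    p_adj stars
#> 1 gamma:F     0.740  0.367 10.9  1.20e-11 3.61e-11 ****
#> 2 gamma:F-C   0.690  0.371 10.1  8.10e-11 2.43e-10 ****
#> 3 gamma:F-Pa  0.493  0.341  4.20 2.46e- 4 7.39e- 4 ***
```

The KTA ranking puts the three class-informative γ-band features (frontal
strength, frontal–central and frontal–parietal communication) at the top of
the 96; leave-one-out SVM classification on them is near-perfect (one error
in 87), the fuzzy clusters reproduce the labels with J ≈ 5, and all three
features separate the groups after Bonferroni correction.

Signal level, with ground-truth coupling:

```r
cp  <- tibble::tibble(band = "gamma", channels = list(c("F3", "F4")), g = 0.75)
sim <- sim_coupled_eeg(cp, duration_s = 60, channels = c("F3", "F4", "Cz"),
                       seed = 1)
round(connectivity_matrix(sim$recording, "gamma")$gamma_vals, 3)
#>       F3    F4    Cz
#> F3 1.000 0.780 0.086
#> F4 0.780 1.000 0.101
#> Cz 0.086 0.101 1.000
```

The partially coupled F3–F4 pair shows strong phase locking while the
uncoupled Cz sits at the estimation noise floor.

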