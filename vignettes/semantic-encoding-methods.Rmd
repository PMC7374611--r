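---
title: "Methods: semantic encoding models for neural film responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semantic encoding models for neural film responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(semenc)
```

This vignette documents the models, the assumptions behind them, and the
design decisions taken where more than one reasonable implementation exists.
It states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. Stimulus features

**Label filtering.** Automatic concept recognizers emit ~20 labels per frame
with probabilities; `filter_labels()` retains labels *strictly above* the
probability threshold (default 0.9 — "more than 90%" is read as a strict
inequality) and inside a curated vocabulary supplied by the caller.
Re-creating the curation itself is out of scope: the keep list is an input.

**Embedding and averaging.** `embed_frames()` looks up each label's
word-embedding vector (300 dimensions by default) and takes the unweighted
mean over a frame's labels. Averaging in embedding space composes meaning:
the mean vector sits in the cosine neighbourhood of all its constituent
labels. Frames that lose all labels to the filter get an all-zero row and a
flag.

**Principal components.** `fit_components()` fits a PCA with column-mean
centering and *no* variance scaling — embedding dimensions share one scale,
so standardizing them would only amplify low-variance directions. Components
are ordered by explained variance. PCA signs are arbitrary; for reproducible
frame rankings we fix the sign so each component's largest-magnitude loading
coefficient is positive. Zero-label frames are excluded from the fit and
scored as the projection of the global mean, i.e. exactly zero; the fit is
over all (non-empty) frames without deduplication.

**Interpretation.** `rank_frames()` takes the top and bottom `fraction`
(default 10%) of frames along a component, ties resolved toward the smaller
frame index in both tails, and tallies label histograms.
`posthoc_label_regression()` fits OLS from the binary label indicators to
the leading component scores; a rank-deficient label design falls back to
the minimum-norm (pseudo-inverse) solution with a warning.

## 2. From raw voltage to HFB amplitude

`hfb_amplitude()` assumes the acquisition band comfortably covers the
analysis band (e.g. 512 Hz sampling for a 60–120 Hz target). The stages:

* Butterworth band-stop notches (order 2, ±2 Hz) at 50 and 100 Hz. The
  original filter type is unspecified in this kind of clinical pipeline;
  zero-phase `filtfilt` avoids phase distortion.
* Complex Morlet wavelets at 1 Hz steps across the band, parameterized by
  temporal FWHM = 4 wavelengths at each centre frequency
  (`sigma_t = 4/(f * 2·sqrt(2·ln 2))`); amplitudes are averaged across bins.
  The wavelet family is the standard choice for a "Gabor decomposition with
  decreasing window length".
* Anti-alias low-pass (Butterworth order 4 at 0.8 × Nyquist of the output
  rate) followed by interpolation at the output frame times — "downsampling"
  is low-pass-then-resample here because 512/25 is not an integer ratio.
* Edges are reflect-padded; the first and last second of output are flagged.

`common_average_reference()` subtracts the instantaneous mean within each
grid (high-density grids separately), excluding bad channels.

## 3. Confound control

The film's audio stream (alternating speech/music blocks, audio envelope)
contaminates visual-semantic modelling. Per electrode,
`residualize_recording()` removes

1. the block design at the lag (grid default ±5 s at the frame period — the
   original grid is unstated) maximizing OLS R², ties toward the smallest
   |lag|;
2. then the envelope at the lag of maximum |cross-correlation| within
   ±`max_lag`.

The two removals are sequential and independent, per electrode. Residuals
are exactly orthogonal to the selected lagged regressor of their own stage.
On the stimulus side, `residualize_features()` projects out
`[intercept, block, envelope]` at lag 0 — the confounds are stimulus-locked,
so stimulus-side lags would be meaningless. Binary-label features are *not*
residualized (categorical 0/1 vectors do not support linear confound
removal), and for comparisons against the binary-label model the component
features should be left unresidualized too.

## 4. The encoding model

`fit_ridge_cv()` predicts each electrode's residual HFB from the
time-shifted component scores by ridge regression:

* **Fold design.** Time series cross-validation leaks through
  autocorrelation if folds are contiguous blocks of one condition.
  `make_fold_plan()` tiles every block into 6 s fragments and deals
  fragments round-robin to 5 folds, so each test set spans both block types;
  inner folds re-deal the training fragments the same way.
* **Solver.** Closed form on standardized features with centering for the
  intercept, via one eigendecomposition of the Gram matrix per training set
  (all λ values and electrodes share it). λ is selected per electrode
  (grid default `10^-3 … 10^6`, 10 log-spaced points) by mean inner-fold
  validation correlation, ties toward the stronger penalty.
* **Outputs.** `r_cv` is the mean over outer folds of the test-set Pearson
  correlation; `betas` are fold-averaged weights on the raw feature scale,
  `betas_std` on the standardized scale. Weight-profile analyses (recovery
  checks, clustering) use the standardized scale: on the raw scale,
  low-variance trailing components multiply coefficient noise by
  `1/sd`, so raw-scale profile correlations are bounded away from 1 even
  for a perfect fit. Activation time courses (dot products with raw scores)
  use the raw-scale weights.
* **Degenerate electrodes** (constant test series) are recorded with
  `r_cv = 0` and flagged.

**Significance.** `significance()` converts r to
`t = r sqrt((n_eff − 2)/(1 − r²))`, two-sided p, Bonferroni over electrodes
(α default 0.001; the stricter 10⁻⁵ display threshold is a parameter, not a
constant). The degrees of freedom after fold averaging are genuinely
ambiguous; the package default estimates `n_eff` per electrode by the
Pyper–Peterman/Bartlett correction
`n / (1 + 2 Σ_k ρ̂_pred(k) ρ̂_obs(k))` from the autocorrelation of predicted
and observed test series (lags up to `min(100, n/5)`, the denominator
clamped at 1, `n_eff` floored at 8). With strongly autocorrelated features
(persistent film scenes) and AR(1) neural noise, the naive frame count is
badly anti-conservative — the global-null calibration in the acceptance
suite is the direct check. `df_method = "frames"` restores the raw per-fold
test length for users who want the uncorrected convention.

**Shift sweep.** `sweep_time_shifts()` refits the full nested CV at every
shift on a grid (default step = one frame period) and returns both summary
curves. The best shift maximizes the significant-electrode count with mean
correlation as tie-break, then the smaller |shift| — with strong feature
autocorrelation the accuracy curve is broad around the true lag, so the
tie-break matters.

## 5. Control models and representational similarity

Pixel features are flat RGB values; Gabor features are quadrature-pair
energies `sqrt(even² + odd²)` over a dyadic pyramid (defaults 4 scales × 8
orientations, frequency `2^j` cycles/image on a `2^j × 2^j` grid, envelope
σ of half a wavelength, luminance input). The even filter is demeaned
(zero DC) so energies ignore luminance offsets — without this the
quadrature phase invariance fails on natural, mean-offset images. The exact
pyramid layout in the complex-cell literature varies; ours is documented
and configurable. Wide feature sets are reduced to 50 principal components
(`reduce_features()`, same PCA contract) before encoding, equalizing model
complexity.

`compare_models()` applies a one-sided Wilcoxon signed-rank test (A > B) to
the paired `r_cv` values over the union of electrodes significant in either
model. P values use the exact signed-rank distribution for fewer than 50
untied pairs and the tie-corrected normal approximation otherwise; with a
few dozen pairs the normal approximation has a p-value floor (|z| saturates
near 4) that an exact test does not.

`representational_similarity()` correlates the upper triangle (diagonal
excluded) of each layer's frame-by-frame Pearson similarity matrix with the
target's. Frames constant in any representation are dropped with a warning
rather than imputed. The bootstrap resamples frames *with replacement*
(standard bootstrap semantics; the alternative subsampling reading of
"sampling 1,000 frames" changes little but is not a bootstrap).
`synthetic_hierarchy()` emulates a deep network's layers as mixtures of one
shared random projection of the target with independent noise at increasing
mixing weights — a single shared projection, because independent per-layer
projections add projection noise that can locally invert the similarity
ordering the construction is meant to guarantee.

## 6. Functional networks

`cluster_betas()` z-scores each weight column over electrodes (asserted),
builds the Pearson affinity of the z-scored profiles, and runs affinity
propagation with damping 0.9, up to 1,000 iterations, and a shared
preference of `min(A) − 2`. A tiny symmetric jitter (seeded, sd 1e-9)
breaks degeneracies. After convergence each exemplar is refined to the
member maximizing summed within-cluster affinity — the brute-force
definition the tests check against. The cluster count *grows* with the
preference (it is each point's self-similarity), which the invariant tests
assert at three preference values. Non-convergence raises a condition
carrying the partial state.

`filter_clusters()` drops subject-specific clusters: retained iff distinct
subjects ≥ `ceiling(n_subjects/3)` *and* no subject holds more than 1/3 of
the electrodes (boundary shares retained; where "a third" and "30%" could
both be read from the source conventions, one third wins).

`peak_dip_null()` shuffles the cluster assignment over electrodes
(default 10,000 times), recomputes the target cluster's exemplar and
activation each shuffle, and pools all baseline activation values; the
2.5th/97.5th percentiles of the *pooled* distribution are the thresholds
(a per-frame variant was considered and rejected as noisier at these
baseline sizes). Candidates beyond the thresholds are reduced to the
top/bottom 10% by activation. Implementation note: only the exemplar choice
varies across shuffles, so per-electrode activation series are cached and a
shuffle costs one exemplar search.

`component_contribution()` pairs peak with dip frames by descending
|activation| rank — the pairing is unstated in the source convention; rank
pairing is deterministic and symmetric — trims to the smaller set, applies
the two-sided signed-rank test per component, Bonferroni over
clusters × components, and reports the statistic additionally divided by
the component's explained-variance percentage (display normalization only;
significance always uses the raw statistic).

## 7. Surface projection

`gp_project()` implements the kernel interpolator
`g = Kc' (Ks + ηI)^{-1} y` with `K = exp(−d²/2σ²)` on great-circle
distances `d = r·arccos(uᵀv)` (dot products clipped to [−1, 1]). Although
the kernel is conventionally called "exponential", the squared distance
inside the exponential is implemented exactly as specified. Defaults
σ = 8 mm (matching the 8 mm FWHM smoothing scale used for the volume
displays; the surface value is unstated) and η = 1e-3; η = 0 with duplicate
electrodes is singular and raises an informative error. `icosphere_grid()`
generates subdivision-order-n icosahedral grids (order 5 ≈ the FreeSurfer
ico5 mesh); any externally supplied point set is accepted.
`combine_subjects()` sums indicator projections ("density") or averages
non-missing values ("mean").

## 8. The synthetic study

`simulate_study()` chains the generators with defaults chosen once to match
the study design:

| parameter | default | rationale |
|---|---|---|
| vocabulary | 129 labels, 8 topics | curated film vocabulary size; topics give the embeddings recoverable similarity structure |
| embedding dim | 300 | the common pretrained word-embedding size |
| labels/frame | 20 | recognizer output size |
| label probabilities | U(0.85, 1) | leaves the 90% filter real work |
| blocks | 13 × 30 s at 25 fps | clinical film task (9,750 frames) |
| `scene_persistence` | 0.96 | ≈1 s median scene persistence at 25 fps; reproduces the strong temporal autocorrelation of film semantics |
| `lag_true` | 0.32 s | planted stimulus-to-response lag (8 frames) |
| `snr` | 1 | semantic signal variance = noise variance per electrode |
| `ar1` | 0.6 | temporally correlated HFB noise at 25 Hz; stresses fold design and significance calibration |
| `frac_null` | 1/3 | electrodes without semantic tuning |
| `confound_gain` | 1 | block/envelope contributions comparable to the signal |
| prototypes | 5, top-5 orthonormal + tail 0.4 | distinct functional networks concentrated on the leading components |

Prototypes and their jitter are planted on the **standardized** feature
scale and divided by the score standard deviations to obtain raw weights.
Two reasons: a weight of 1 then always means "one standard deviation of
that component's score", and every planted contribution is estimable —
planting raw-scale weights on near-zero-variance components creates
structure the data cannot carry, which no estimator could recover and which
the clustering's z-scoring would turn into amplified noise. Prototypes also
carry a weak structured tail (norm 0.4) beyond the top five components,
because real encoding profiles are never exactly zero off their preferred
axes and all-zero columns would again z-score into pure noise.

**What the generator does not emulate:** realistic film imagery (frames are
label-keyed procedural gratings — sufficient for low-level feature
controls, nothing more), raw broadband field potentials (HFB is generated
directly at the frame rate; `hfb_amplitude()` is tested on analytic
signals), non-Gaussian or non-stationary noise, electrode localization
error, and inter-subject variability in tuning. Passing recovery tests
therefore demonstrate the pipeline's correctness and calibration under the
planted generative model, not performance on real cortex.

## 9. Problem sizes and numerical tolerances

The test suite and acceptance script run the full stimulus geometry
(9,750 frames, 60 electrodes over 10 subjects, 50 components) with a
60-dimensional embedding lexicon — the component spectrum, not the raw
embedding dimension, is what the downstream stages see, and 60 dimensions
keeps a full nested-CV shift sweep at a few seconds per shift. Calibration
checks use 10–20 independent noise realizations on a fixed stimulus (the
film is fixed in the design; neural noise is the relevant randomness) and
500 replicates for the rank-test calibrations. Oracle equivalences are
asserted at 1e-8 (ridge vs normal equations), 1e-10 (surface projection vs
direct formula, RSA vs loop oracle) and exact index arithmetic for the lag
oracle. Seeds derive from a single user seed via a fixed linear map and
stay within 32-bit integer range.

## 10. Known limitations

* The Bartlett-corrected `n_eff` is an estimate; at very short test folds
  it is floored and the t approximation coarsens.
* Affinity propagation with `min(A) − 2` can merge planted networks when
  profile noise is large relative to the affinity gaps; the preference is
  exposed for sensitivity analysis.
* The permutation null shuffles whole-electrode assignments only; it does
  not model within-electrode temporal uncertainty.
* `hfb_amplitude()` processes channels independently in R loops; very large
  channel counts would warrant a compiled path.
* The GP projection solves a dense E × E system; it targets per-subject
  electrode counts (≤ a few hundred), not whole-brain vertex sets.
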