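---
title: "Methods: circularity of task-congruent neural geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: circularity of task-congruent neural geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geomstate)
```

## The model

A working-memory manipulation design crosses two binary goal dimensions
(size: bigger/smaller; color: redder/greener), so the four goals occupy the
corners of a square in an abstract 2D goal space; remembered stimuli occupy
a 3×3 grid of size × color bins. The question the package answers is
whether neural population activity arranges the condition representations
in that same layout.

The estimator is a pipeline of five steps applied per time window:

1. **Condition averaging.** Trials are averaged within condition after
   averaging the signal over the window, giving an
   `n_conditions × n_channels` matrix.
2. **Standardization.** Each channel is z-scored across conditions
   (zero-variance channels are set to zero loading rather than dropped, so
   channel indexing never shifts).
3. **PCA.** The top two principal components of the standardized matrix
   define the condition subspace. Scores are projections onto the
   unit-norm components *without whitening*: whitening would force every
   layout toward a circle and inflate the statistic.
4. **Polygon construction.** Conditions are connected in the fixed order
   of the designed space — goals as the square walk
   bigger_redder → bigger_greener → smaller_greener → smaller_redder;
   stimuli (after dropping the middle color bin, leaving 3 sizes × 2
   colors) as the perimeter walk of the grid, the only order in which
   grid-adjacent conditions are polygon-adjacent. Vertex order is never
   inferred from data.
5. **Circularity.** `C = 4π·|A|/P²` with `A` the signed shoelace area of
   the vertex cycle and `P` the edge-length sum. A circle gives 1, a
   square π/4 ≈ 0.785 (the quadrilateral maximum), collinear or collapsed
   layouts 0. Self-intersecting cycles are scored by the absolute signed
   area of the fixed cycle, which collapses toward zero — deliberate,
   because a crossed layout is exactly what a task-incongruent geometry
   looks like under the fixed vertex order. If the perimeter is zero the
   statistic is defined as 0.

`C` is exactly invariant to translation, rotation, reflection and uniform
scaling of the projected vertices. It is *not* invariant to arbitrary
orthogonal rotations of channel space: per-channel z-scoring singles out
the channel basis. That is a property of the method, shared with the
standardize-then-PCA convention it follows.

## Inference

- **Time course.** The −500…4300 ms epoch (250 Hz) is tiled into
  non-overlapping 80-ms windows anchored at the epoch start (60 windows;
  trailing partial windows are dropped). Per window the pipeline runs on
  `n_resamples` stratified bootstrap resamples (within-condition, with
  replacement, preserving per-condition counts) and the resample mean is
  reported. Resampling with replacement is used because it gives valid
  variance at small per-condition counts.
- **Cluster permutation.** Labels are shuffled within subject; the same
  resampling protocol is applied to every shuffle; subject curves are
  averaged into one null curve per iteration. Windows above the pointwise
  95th null percentile form clusters, scored by *run length* (window
  count); a cluster is significant when its length exceeds the 95th
  percentile of the per-iteration maximal null run. Per-window and pooled
  pointwise thresholds are both implemented (`pointwise` argument);
  per-window is the default.
- **Trial splits.** Good/bad trials are the bottom/top quartiles of the
  combined error (sum of z-scored absolute size and color errors; if one
  error has zero variance, the other alone is used with a warning). Both
  subsets are projected into a subspace fit on *all* trials per window, so
  the comparison is made in a common space. A median split is required
  when quartiles cannot cover all conditions (the 6-condition stimulus
  hexagon). The null swaps good/bad assignments; the difference is tested
  two-sided by default (`alternative = "greater"` available), through the
  same cluster machinery.
- **RSA.** The 2D goal model counts mismatched goal dimensions
  (0, 0.5, 1); the conjunctive model is equidistant (0/1). At the 4-goal
  level the conjunctive distance vector is constant, so competitive
  comparisons require conditions defined as goal × stimulus cells
  (`expand_model_rdm`). Data RDMs use cross-validated correlation distance
  over stratified folds, averaged over all ordered disjoint fold pairs so
  the matrix is exactly symmetric; negative distances are retained
  (cross-validation makes the estimator unbiased but not positive).
  Spearman ties get average ranks; the partial-Spearman variant partials
  each model on the others via the inverse rank-correlation matrix, with a
  1e-10 ridge fallback when the data vector coincides exactly with a model.
- **Coherence.** Complex Morlet wavelets (5 cycles, 1–12 Hz in 1-Hz
  steps) give per-epoch seed→target cross-spectra;
  wPLI = |E[Im S]| / E[|Im S|] over epochs (cells with E[|Im S|] = 0 set
  to 0), averaged over target channels after the per-pair computation.
  Baseline correction subtracts the per-frequency mean over −500…0 ms.
  Group inference is a one-sample, one-tailed sign-flip cluster test in
  the time–frequency plane (4-adjacency, summed-t cluster mass — the
  standard statistic for that routine, whereas the time-course test uses
  run length per its own convention). Theta submasks restrict significant
  clusters to 4–7 Hz for per-subject strength extraction.
- **Searchlight.** Spheres of 9-mm radius (center-to-center distance,
  inclusive; clipped at mask edges) run the same five-step pipeline with
  voxels as channels. Group correction: per-subject label-shuffle maps,
  bootstrap draws picking one shuffled map per subject, voxelwise p at
  α = 0.01 against that null, face-adjacency clusters, and a cluster-size
  threshold from the null draws' maximal cluster sizes.

## The synthetic-data generator

The generator is first-class, tested code: it plants a known geometry so
every downstream stage is checked by parameter recovery.

- **Design.** 4 goals × 9 stimulus cells × 18 repetitions = 648 trials in
  12 blocks, exactly counterbalanced, order a seeded permutation. The
  color ladder arithmetic (150 raw variants − 30 discarded extremes = 120
  usable steps) and the stimulus bin centers (0.17/0.22/0.27 of screen
  height; color steps 34/58/82) follow the task's construction, as do the
  learned adjustment magnitudes (±24 % of size, ±26 color steps).
- **Signal model.** A 2D latent coordinate per condition is mixed linearly
  into channels and gated by a piecewise-constant activation profile over
  the task epochs (goal cue 0–400, delay 1 400–1700, sample 1700–2300,
  delay 2 2300–3800, response 3800–4300 ms), plus i.i.d. Gaussian noise.
  `snr` is the ratio of across-condition signal variance (per carrying
  channel, within the active window) to noise variance.
- **Balanced mixing.** Loading rows are an equiangular frame with a random
  phase offset and random channel assignment: equal row norms and exactly
  orthonormal columns. Because both planted layouts (square, 3×3 grid)
  have isotropic latent covariance, per-channel z-scoring then acts as a
  uniform scaling and the noise-free pipeline returns the analytic
  circularity exactly. A generic random mixing would shear the square
  through the standardization step and make "exact recovery" unattainable
  by construction, which would test the generator rather than the method.
  The 6-condition stimulus hexagon has *anisotropic* latent covariance
  (axis variances 0.8 vs 1.2 over its vertices), so its recovery is close
  to, but not exactly, the analytic value — tests assert qualitative
  recovery there.
- **Behavior.** Error magnitudes start from the observed mean absolute
  errors (0.133 of starting size; 10.1 color steps), are shifted down by
  `coupling ×` the standardized per-trial geometry strength, noised, floored
  at zero and given random signs. Coupling acts on signal gain, not label
  identity, preserving exchangeability under the null. Response-object
  start values are drawn symmetrically around the correct target so the
  motor adjustment direction is 50/50 regardless of the cued goal — the
  property the motor-relabeling control analysis requires.
- **What is not emulated.** No oscillatory background or 1/f spectrum, no
  channel covariance beyond the planted plane, no artifacts, no trial
  rejection, no hemodynamics (beta volumes are condition patterns plus
  white noise). Passing recovery tests therefore shows the *estimator and
  inference machinery* are correct under the stated signal model, not that
  real recordings meet that model.

## Parameters and presets

| parameter | default | units | note |
|---|---|---|---|
| window length | 80 | ms | 60 windows over −500…4300 ms |
| `n_resamples` | 10 (scaled: 5) | — | stratified bootstrap per window |
| `n_perm` | 5000 (scaled: 500) | — | label shuffles for the null |
| `n_bootstrap` | 10000 (scaled: 500) | — | group searchlight null draws |
| label shuffles/subject | 100 (scaled: 20) | — | searchlight permuted maps |
| α (pointwise & cluster) | 0.05 | — | one-sided for circularity |
| voxel α | 0.01 | — | searchlight voxelwise threshold |
| sphere radius | 9 | mm | ≥ voxel size required |
| wavelet cycles | 5 | — | Morlet; 1–12 Hz in 1-Hz steps |
| coherence baseline | −500…0 | ms | per-frequency subtraction |
| theta band | 4–7 | Hz | cluster submasks |

`analysis_config(preset = "full_scale" | "scaled_down")` resolves every
defaulted numeric parameter; runs write the resolved configuration beside
their outputs so any number in a report can be traced to its settings.

## Numerical choices and degenerate inputs

- Zero perimeter → C = 0; fewer than 3 vertices → error; self-intersection
  → |shoelace| of the fixed cycle (see above).
- Zero-variance channels → zero loading (indexing stable).
- Fewer than 3 conditions → degenerate-input error; 4 identical rows →
  all-zero scores → C = 0.
- wPLI cells with E[|Im S|] = 0 → 0; single epoch → error.
- Constant correlation inputs → flagged undefined and excluded from the
  BH family.
- Cross-validated RDM: `standardize = TRUE` (the default) z-scores
  channels across trials first. This removes condition-invariant patterns
  and couples fold means slightly (negatively), so the pure-noise
  expectation of the distance sits above 1; with `standardize = FALSE`
  the classical expectation of 1 holds. Both behaviors are tested.
- All randomness flows from one seed through a documented splitting scheme
  (`split_seed`); identical seeds give byte-identical outputs.

## Test problem sizes

The suite validates calibration and recovery at sizes chosen to make the
Monte-Carlo error small while keeping a full run inexpensive: familywise
error of the cluster pipeline over 200 null runs (72 trials, 8 channels,
20 windows, 500 permutations each); Delay-1 cluster detection over 10
seeds at SNR 1 on the full 648-trial design; searchlight localization with
8 subjects on a 20³ grid with 20 shuffles per subject and 500 bootstrap
draws; 10 000 random simple quadrilaterals for the isoperimetric bound.
The trial-split recovery fixture uses a per-sample SNR of 0.01: window
averaging (20 samples) and ~160-trial condition means raise effective SNR
by orders of magnitude, and at higher per-sample SNR both error quartiles
saturate at the π/4 ceiling, leaving no behavioral difference to detect.

## Known limitations

- The group-concatenated projection (`group_concat_projection`) is a
  visualization helper only, not a validated inference path.
- Partial-Spearman significance is pointwise (per window), uncorrected,
  matching the convention of time-resolved competitive RSA.
- The coherence module's wavelet parameters and baseline window are
  package defaults, exposed in the configuration; its outputs are
  validated by planted-coupling recovery and null calibration, not against
  any reference cluster extents.
- No preprocessing (filtering, artifact handling, GLM fitting, spatial
  normalization) is provided; the package starts at epoched channels or
  trial-wise betas.
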