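# geomstate

Quantifying task-congruent geometry in neural state space.

In working-memory manipulation tasks, the four goals formed by crossing two
binary goal dimensions (adjust size bigger/smaller × adjust color
redder/greener) define a theoretical 2D goal space in which the goals sit at
the corners of a square; the remembered stimuli (3 size bins × 3 color bins)
define a 3×3 grid. `geomstate` tests whether multichannel neural activity
(EEG epochs, or trial-wise fMRI beta volumes) represents these variables in
the same low-dimensional layout, and whether the strength of that layout
matters for behavior and inter-regional communication. It is written for
cognitive/systems neuroscientists analyzing condition-rich working-memory
designs.

## The statistic

For a window of data, trials are averaged within condition to give a
condition × channel matrix. Each channel is z-scored across conditions, the
top two principal components are taken, and the conditions are projected
into that plane. The projected points are connected **in the fixed order of
the designed space** (goals: bigger-redder → bigger-greener →
smaller-greener → smaller-redder), and the resulting polygon is scored by
the circularity index

```
C = 4π · Area / Perimeter²
```

A circle has C = 1; a square has C = π/4 ≈ 0.78, which is also the maximum
over quadrilaterals, so a square-like goal geometry drives C toward 0.78
while collapsed or crossed ("bow-tie") layouts fall toward 0. Inference
uses within-subject label-shuffle permutations with cluster-based
correction over time (cluster statistic = run length of supra-threshold
80-ms windows). Around this core the package provides:

- a synthetic-data generator that plants known goal/stimulus geometries into
  channels or voxels at a controlled SNR, so every stage is validated by
  parameter recovery;
- behavioral coupling analyses: quartile/median trial splits in a shared
  whole-data subspace, and Spearman correlations with FDR control;
- representational similarity analysis with the 2D (Hamming 0/0.5/1) and
  conjunctive (equidistant) goal models, cross-validated correlation-distance
  data RDMs, and Spearman / partial-Spearman model comparison;
- theta-band seed-to-posterior coupling via the weighted phase-lag index
  wPLI = |E[Im S]| / E[|Im S|], with one-sample sign-flip cluster tests in
  the time–frequency plane;
- a volumetric searchlight (9-mm spheres) running the same circularity
  pipeline per voxel neighborhood, with group correction by per-subject
  label shuffles and subject-level bootstrap, ROI bootstrap robustness, and
  beta-series functional connectivity.

## Worked example

Simulate one subject's 648-trial session with a square goal geometry active
during the first memory delay at SNR 1, then estimate and test the
circularity time course:

```r
library(geomstate)

trials <- generate_design(design_spec(), seed = 1)           # 648 trials
geom   <- goal_square_geometry(n_channels = 16, snr = 1,
                               activation = activation_profile("delay1"),
                               seed = 1)
epochs <- generate_epochs(trials, list(goal = geom), n_channels = 16,
                          noise_sd = 1, seed = 1)            # 250 Hz, -500..4300 ms
labels <- goal_labels(trials)

tc   <- timecourse_circularity(epochs, labels, n_resamples = 5, seed = 1)
null <- permutation_null(epochs, labels, n_perm = 500, n_resamples = 5, seed = 2)
cluster_test(tc, null)
#> cluster_set: 4 cluster(s), 1 significant (cluster threshold 3 windows)
#>   start end size     p significant
#> 1     7   7    1 0.914       FALSE
#> 2    12  28   17 0.018        TRUE
#> 3    35  35    1 0.914       FALSE
#> 4    40  40    1 0.914       FALSE
```

The one significant cluster spans windows 12–28, i.e. 380–1740 ms: the
planted Delay-1 geometry (400–1700 ms) is recovered to within one 80-ms
window. Inside it the mean circularity is 0.785 ≈ π/4 (the planted square);
in the pre-cue baseline it averages 0.249, the chance-level geometry of
noise-only condition means. `run_pipeline(analysis_config())` chains the
same stages and writes `curve.tsv`, `tc.json` and a reproducibility
manifest.

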