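---
title: "Models and methods behind netdisrupt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind netdisrupt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(netdisrupt)
```

`netdisrupt` compares resting-state and block-design task fMRI between two
small cohorts (controls versus an injured group) and localizes functional
connectivity disruptions to networks and anatomical structures. This
vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what the synthetic phantom does and does not show.

## The two decomposition paths

### Sparse dictionary learning with dual regression

Each group dataset is a voxels-by-time matrix `s` formed by temporally
concatenating the trimmed runs of that group's subjects. `sdl_fit()`
minimizes, over a temporal dictionary `D` with unit-norm columns (the
constraint set `C`) and per-voxel codes `α`,

$$\min_{D \in C} \sum_j \min_{\alpha_j}
  \tfrac12 \lVert s_j - D\alpha_j \rVert_2^2 + \lambda \lVert \alpha_j \rVert_1.$$

The inner problem is the LASSO; `sparse_code()` solves it per voxel by
cyclic coordinate descent with soft-thresholding updates against the
precomputed Gram matrix, to a coefficient-change tolerance of `1e-6` and at
most 1000 sweeps. The outer problem alternates sparse coding with a
Gauss–Seidel dictionary update: with codes fixed, the reconstruction error
is linear in each atom and its minimizer on the unit sphere has the closed
form `d_k = E_k a_k / ‖E_k a_k‖`, where `E_k` is the residual excluding atom
`k` restricted to the atom's active voxels. Because each step minimizes the
objective in one block, the recorded objective is non-increasing across
outer iterations — a property the test suite asserts on every run. Atoms
that lose all active voxels are re-seeded from the residual time courses of
the worst-reconstructed voxels, one distinct voxel per dead atom; this is
objective-neutral (their codes are zero) and is what lets a fit recover a
network that the random initialization happened to miss.

Per-subject maps come from `dual_regression()`: stage 1 solves
`s_i = D_i α_g` for the subject dictionary by ordinary least squares
(a rank-deficient Gram matrix falls back to a ridge jitter of `1e-8` with a
warning) and renormalizes its columns; stage 2 sparse-codes the subject's
data against `D_i` with the same `λ`.

### The data scale behind λ = 0.15

A LASSO weight is only meaningful relative to the scale of the data. With
unit-norm atoms and voxel time series scaled to unit Euclidean norm, the
atom–signal inner products that drive the soft threshold are bounded by 1
and `λ = 0.15` acts as a correlation floor: a voxel loads on an atom only if
their correlation exceeds 0.15. We adopt exactly this convention — the one
used by the sparse-modeling toolboxes this formulation descends from — and
the pipeline therefore scales every voxel's within-subject time series to
unit ℓ2 norm before decomposition (`concatenate_group(scale_voxels =
TRUE)`). The alternative of unit-variance series leaves the ℓ1 term
negligible for realistic run lengths (inner products grow like √T), the fit
degenerates toward an unpenalized factorization that is
rotation-indeterminate, and network recovery becomes unstable across
initializations; we observed exactly this failure mode and regard the
unit-norm convention as the defensible reading. The scaling is a switch, not
a hard-coded transform, and the metrics downstream are invariant to it.

### Group ICA with back-reconstruction

`group_ica()` performs spatial ICA: the group matrix is reduced to
`n_components` temporal principal components (eigendecomposition on the
smaller side of the matrix), the reduced spatial data are whitened, and a
fixed-point iteration with the log-cosh contrast and symmetric decorrelation
(tolerance `1e-6`, at most 1000 iterations, warning on non-convergence)
yields maximally non-Gaussian, mutually decorrelated spatial maps.
`back_reconstruct()` obtains subject maps by projecting each subject's
partition of the reduced data through the inverse of the group unmixing,
scaled by the number of subjects; a single-subject "group" then reproduces
the group maps exactly, which the tests assert. The fixed-point ICA with a
log-cosh contrast was chosen over an explicit Infomax gradient scheme as the
standard deterministic-under-seed formulation of the same
maximum-non-Gaussianity objective.

### Sign convention

Both decompositions are sign-indeterminate per component. Every component
(ICA and sDL) is flipped so the voxel of maximum absolute weight is
positive, applied jointly to the map and its time course so reconstructions
are unchanged. Some convention is required for the positive-tail z-threshold
below to be meaningful; this one needs no reference data.

## Atlas-referenced statistics

Subject maps are divided by the maximum absolute group activation value of
the corresponding group fit (`group_max()`), converted to voxelwise
z-scores over the in-brain population of each map, and voxels below `z = 1`
are zeroed (`normalize_and_threshold()`). Z-scores use the population SD
(denominator `n`); survivors keep their normalized value, so downstream
metrics see both extent and magnitude. Both metrics are computed on the
normalized, thresholded maps, matching the stated order of operations
(normalize, threshold, then correlate); the threshold and `z_cut` are
exposed for sensitivity analyses.

For each network atlas, `select_maximal_map()` picks the ICA component with
the largest Pearson correlation against the binary atlas indicator, or for
sDL averages the three distinct top-correlated atoms (ties break to the
lowest component index) and recomputes both metrics on the averaged map.
The mean ratio is mean activation inside the atlas over mean activation
outside it; a zero outside-mean marks the value undefined (`NA`) rather than
raising an error, and undefined values are dropped (with a count) before
testing. The Pearson reference is the binary indicator; a weighted template
would be a one-line change but the binary reading is the literal one.

Group differences are assessed per region with Welch's unequal-variance
t-test (`welch_test()`, statistic `mean_C − mean_T`, two-sided p, a `1e-12`
variance floor guarding degenerate inputs). A region is reported as
significantly different only when *both* the Pearson and mean-ratio
p-values fall below 0.05 and the directions agree — the dual-metric rule.
The cerebellar network is reported at network level only; its lobes are not
examined separately.

## The exhaustive permutation test

`voxelwise_permutation()` enumerates all `C(N_C + N_T, N_C)` assignments of
the subjects into pseudo-groups of the original sizes (792 for 7 vs 5) and
computes the voxelwise mean difference `T = mean_C − mean_T` under each.
"Among the largest five percent" is operationalized as a rank p-value
`#{T_perm ≥ T_actual}/n_perm ≤ α` with the true assignment included in the
reference set and ties counted against rejection (symmetrically for the
increase direction); near-ties within a relative tolerance of `1e-8` of the
map scale are treated as ties so that voxels constant across subjects are
never flagged. Consequences the tests verify: the attainable p-value is
floored at `1/n_perm`, designs as small as 2-vs-1 can never reach α = 0.05,
relabeling the groups negates `T` and exchanges the flag directions, and
under exchangeable null maps the flag rate at α = 0.05 equals the largest
achievable level below it (39/792 ≈ 0.0492 for 7 vs 5). Tests run over all
in-brain voxels; percentages of flagged voxels are then reported within each
network and structure. No multiple-comparison correction is applied, by
design: with at most 792 permutations the smallest attainable p-value
(1/792) is too large for meaningful correction across thousands of voxels,
so uncorrected tails with a declared ~5% false-positive rate are the honest
summary.

One subtlety the calibration test respects: per-subject maps that have been
through *group-wise* model fits are not strictly exchangeable across groups
(each map depends on which group's dictionary produced it — true of the
original design as well). The type-I calibration check therefore feeds the
permutation machinery per-subject maps computed independently per subject
from identically distributed null phantoms, where exchangeability holds
exactly and the binomial envelope around the nominal rate is the right
yardstick.

## The synthetic phantom

`make_phantom_atlas()` builds an ellipsoidal brain (semi-axes 0.45 of the
grid, ≥ 2400 in-brain voxels at the default 24×24×16 grid — comparable to
the voxel counts such studies evaluate) and places 17 blob-shaped,
non-overlapping structures: 3 visual, 7 executive-control and 3
sensorimotor structures with their standard anatomical names, plus single
placeholder structures for the cerebellar, default-mode, salience and
basal-ganglia networks. Placement is seeded rejection sampling that falls
back to the smallest blobs when packing gets tight and fails loudly, naming
the structure, if the grid cannot host all 17.

`make_design()` encodes the acquisition timing: TR = 3 s; resting runs of
305 volumes; task runs with 15 s dead time followed by six 30 s ON / 30 s
OFF cycles (125 volumes). The block regressor is the boxcar convolved with
the canonical double-gamma HRF (`dgamma(t, 6, 1) − dgamma(t, 16, 1)/6`,
peak-normalized), sampled at TR.

`simulate_subject()` gives each network one shared latent time course —
band-limited (0.01–0.1 Hz) Gaussian fluctuation at rest, the regressor plus
a small fluctuation (amplitude 0.2) for task-driven networks — and each
voxel records `baseline + amplitude × jitter × factor × latent + AR(1)
noise`. Defaults: baseline 100 and amplitude 1 against noise SD 1 (a ~1%
BOLD fluctuation at unit SNR, typical of resting-state data), lag-1
autocorrelation 0.3 so the permutation machinery is exercised under temporal
autocorrelation, and a per-subject log-normal amplitude jitter of SD 0.1.
The shared within-network course is precisely what makes networks
recoverable by decomposition; independent courses across networks make them
separable. The injury effect is multiplicative on fluctuation amplitude —
attenuation in damaged structures, elevation in compensating ones —
mirroring the hypoactivation/hyperactivation framing of such studies. No
quantitative effect sizes exist to copy, so the defaults (attenuation 0.3–
0.4 in visual and executive structures, elevation 1.5 in two compensating
structures) are free parameters of the configuration, not claims about
biology.

What the phantom does **not** emulate: realistic neuroanatomical geometry,
susceptibility or motion artifacts, physiological (cardiac/respiratory)
noise, inter-subject registration error (the phantom lives in one shared
space; registration is the identity), or between-network correlation.
Passing tests therefore demonstrate that the pipeline's machinery is
correct and calibrated under its stated assumptions — not that those
assumptions hold in any particular acquisition.

## Parameters at a glance

| parameter | default | meaning |
|---|---|---|
| `tr` | 3 s | volume sampling interval |
| `rest_volumes` / task timing | 305 / 15 s + 6×(30+30) s | run lengths (125 task volumes) |
| `trim` | 5 volumes | magnetization-equilibration discard |
| `lambda` | 0.15 | LASSO weight; correlation floor under unit-norm signals |
| `n_atoms` | 300 rest / 120 task | dictionary size = run length (complete dictionary) |
| `n_components` | 70 | ICA model order |
| `z_cut` | 1 | map z-score threshold |
| `alpha` | 0.05 | per-metric and permutation significance level |
| `ar1` | 0.3 | noise lag-1 autocorrelation |
| `noise_sd`, `amplitude` | 1, 1 | noise and network fluctuation scale |

## Problem sizes and determinism

The bundled demo configuration (`demo_config()`) runs the entire
simulate-to-report pipeline on an 18×18×16 grid with 4+3 subjects per
paradigm, 100-volume resting runs, a 2-cycle task, 20/16 atoms and 8 ICA
components — minutes of single-CPU work — while the full-scale settings
remain the defaults of `netdisrupt_config()`. The test suite exercises
full-length runs (305/125 volumes, 7-vs-5 cohorts) for the dataset
arithmetic, calibration and planted-effect recovery checks, and reduced
dictionaries (40 atoms) where full ones would add runtime without changing
what is being verified. Every stochastic step — atlas placement, simulation,
dictionary initialization, ICA initialization — is a deterministic function
of its seed, and pipeline reruns reproduce artifact checksums exactly.

## Known limitations

* The optimizer for the dictionary objective is block coordinate descent;
  it finds a local optimum, and different seeds can find different (equally
  valid) dictionaries. The maximal-map selection step absorbs most of this
  variability; the objective trace, not the atom identities, is the stable
  quantity.
* Back-reconstruction follows the single-stage-PCA formulation; toolboxes
  that reduce per subject before a second group reduction will differ in
  detail, though degenerate cases coincide.
* With cohorts this small the Welch tests are low-powered and the
  permutation p-value floor is 1/792; the package reports both routes
  precisely because each is susceptible to a different error type.
* Undefined mean ratios (zero outside-mean after thresholding) are dropped
  from tests with a count; heavily thresholded maps can reduce the
  effective sample size per region.
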