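---
title: "Methods: nodal centrality and seed connectivity in density-thresholded brain graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nodal centrality and seed connectivity in density-thresholded brain graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremornet)
```

## The scientific problem

Resting tremor in Parkinson's disease is thought to arise from hyperactivity
of the cerebello-thalamo-motor-cortical loop, with the thalamus acting as a
pacemaker-like relay. If that is true, the thalamus of a tremor-dominant
patient should look more *central* in the whole-brain functional network:
more connections, more shortest paths routed through it, and more links
reaching outside its own network module. `tremornet` implements the full
analysis chain needed to test that idea on region-of-interest (ROI) BOLD
time series: time-series cleaning, density-thresholded binary graph
construction, four nodal centrality metrics over modularity partitions,
repeated-measures group statistics, clinical correlations, and an ROI-level
seed-connectivity contrast — plus a synthetic cohort generator so the whole
chain can be validated without clinical data.

## Preprocessing model

Each subject contributes a T x N matrix of ROI signals (defaults: N = 92
atlas regions — the 90 cerebral AAL regions plus one cerebellar composite
per hemisphere — at TR = 2 s) and a nuisance table of six rigid-body motion
parameters plus mean white-matter (WM) and cerebrospinal-fluid (CSF)
signals. Cleaning follows a fixed order:

1. **Initial-volume discard** (default 10 volumes) removes the
   scanner-equilibration period; with 185 acquired volumes this retains 175.
2. **Nuisance regression**: ordinary least squares of every node on the
   24-parameter motion expansion (6 parameters, their backward differences
   zero-padded in the first row, and the squares of those 12), WM, CSF, and
   an intercept — 27 regressors. Residuals are exactly orthogonal to the
   design; collinear columns are dropped with a warning rather than
   inverting a singular system.
3. **Band-pass filtering** of the residuals with a second-order Butterworth
   applied forward and backward (zero phase), default band 0.01–0.08 Hz.
   Columns are demeaned before filtering; the DC term is outside the
   passband and removing it first avoids start-up transients of the
   forward-backward pass.

Regression precedes filtering because filtering the nuisances but not the
signal (or vice versa) can reintroduce artifact at the regression step.

Motion quality control summarizes each subject by the summed
volume-to-volume translational excursion (root-mean-square across axes,
mm), the summed rotational excursion (degrees), and mean framewise
displacement. The FD here is the standard scalar convention — absolute
translation steps plus rotation steps scaled by a 50-mm head radius — since
a voxel-level displacement cannot be reconstructed from six parameters
alone; this is documented as a convention, not an approximation error.

## Graph construction

Pearson correlations between all node pairs give a symmetric N x N
connectivity matrix (diagonal fixed to zero; zero-variance nodes get zero
rows with a warning). The matrix is binarized over a grid of connection
densities, default 0.10 to 0.40 in steps of 0.01 (31 graphs), the range in
which resting-state networks retain small-world organization. At density
*d* the `round(d * N(N-1)/2)` largest signed correlations become edges:

- **Signed thresholding** keeps the strongest positive correlations, the
  common practice for binary resting-state graphs; an `absolute = TRUE`
  switch is available. Whether negative correlations can enter the edge set
  at high densities is data-dependent and left to the user's choice of
  mode.
- **Rounding** to the nearest integer is used for the edge count; floor
  versus round changes counts by one, so the choice is fixed and tested.
- **Ties** in correlation are broken by upper-triangle position order, so
  thresholding is deterministic; with continuous data ties have measure
  zero.
- Edge sets are **nested** across densities by construction, and
  thresholding is rank-based: any strictly increasing transform of the
  correlations (e.g. Fisher z) yields identical graphs.

Disconnected graphs at low densities are legal; no connectedness repair is
applied.

## Centrality and modularity

Four nodal metrics are computed per density:

- **Degree** `K_i`: the node's edge count.
- **Betweenness** `B_i`: the summed fraction of all-pairs shortest paths
  passing through the node. Ordered source–target pairs are counted, so
  each unordered pair contributes twice; only group contrasts matter, so
  the factor is fixed and documented, with an optional normalization by
  `(N-1)(N-2)`.
- **Within-module degree** `Z_i`: the z-score of the node's intra-module
  degree against its own module's intra-module degree distribution,
  population standard deviation. `Z = 0` when the module's spread is zero
  (including singleton modules).
- **Participation coefficient** `P_i = 1 - sum_m (K_im / K_i)^2`: 0 for a
  provincial node, approaching 1 for a connector hub; `P = 0` for isolated
  nodes by convention.

`Z` and `P` require a modular partition. Partitions are found by Louvain
modularity maximization with `n_restarts` (default 100) randomized node
orders, keeping the partition with maximal Newman modularity

$$Q = \frac{1}{2m} \sum_{ij} \left(a_{ij} - \frac{k_i k_j}{2m}\right)
      \delta(c_i, c_j).$$

Louvain is used rather than Newman's original spectral heuristic because
any Q-maximizer satisfies the contract and Louvain is fast enough for 31
densities x subjects x restarts; the restart stream is seed-controlled, and
with a fixed seed a larger restart count extends the same stream, so the
returned Q is non-decreasing in `n_restarts`. Partitions are recomputed
per density because the graphs differ per density; an edgeless graph gets a
single-module partition with Q defined as 0.

The group-level modular summary averages connectivity matrices within a
group, thresholds the mean matrix at one density (default 0.30), partitions
it, and lists each query node's neighbors as same-module versus
other-module — the table from which a hub's gained intermodular links are
read off.

## Group statistics

The group effect on a node's metric is tested with a repeated-measures
ANCOVA: density is the within-subject factor, group (TP / NTP / HC) the
between-subject factor, and mean-centered age plus binary sex are
covariates. The model is fit as a multivariate linear model over the
density columns with type-III sums of squares and sum-to-zero group
contrasts — the standard GLM repeated-measures route — and
Greenhouse-Geisser-corrected p-values are reported for within-subject
terms (sphericity across 31 densities is implausible). The between-subject
group test is the reported effect. A two-stage formulation (residualize
covariates, then mixed ANOVA) is algebraically close but not identical
under unbalanced groups; the full model was chosen because it is exact and
matches the behavior of mainstream statistics packages, and the classical
equivalence (balanced two groups, no covariates: between-subject F equals
the squared two-sample t on density-averaged values) is verified in the
test suite.

Post hoc pairwise group contrasts are computed on density-averaged,
covariate-adjusted values via estimated marginal means. The density-wise
alternative is ambiguous in common practice; the averaged convention
matches how the clinical correlations are defined. No multiplicity
correction is applied across nodes, metrics or scores: the hypothesis nodes
are a priori and the metrics are strongly interdependent, and every report
records this policy.

Clinical associations use partial Pearson correlations: residualize both
the density-averaged metric and the score on age and sex (with intercept),
correlate the residuals, and refer `r sqrt(df / (1 - r^2))` to a t
distribution with `n - 2 - k` degrees of freedom. Derived scores follow the
standard UPDRS item arithmetic (resting tremor = item 20; total tremor =
items 16 + 20 + 21; bradykinesia = items 23–26; rigidity = item 22).

## Seed connectivity

The ROI-level analog of voxelwise seed connectivity regresses every
non-seed node on the seed regressor — the unweighted mean of a bilateral
ROI pair (hemispheric dominance is not modeled) — jointly with the
24-parameter motion expansion, WM and CSF. The per-subject seed betas then
enter a covariate-adjusted two-group contrast over an a priori mask
(default: bilateral thalami). Family-wise error over the mask is controlled
by the permutation distribution of the maximum absolute t under group-label
exchange with covariates held fixed (default 5,000 permutations). This
replaces random-field small-volume correction, which has no meaning at ROI
level; the permutation max-statistic is exact for the ROI family. Peak-level
inference is used: the peak is the mask node with the largest absolute t,
and its beta feeds the clinical partial correlations.

## The synthetic cohort generator

The generator draws each subject's series from a zero-mean multivariate
Gaussian whose correlation matrix has block-modular structure:
`within_module_corr` (default 0.5) on diagonal blocks,
`between_module_corr` (default 0.1) elsewhere. One designated hub node has
its correlations toward out-of-module nodes raised by `hub_boost` (default
0.25) plus subject-level Gaussian jitter (SD 0.08) in affected groups
(default TP only). Because the hub edit can break positive
semi-definiteness, the matrix is repaired by clipping eigenvalues at a
small positive floor and rescaling to unit diagonal; generation fails
loudly if the repair does not converge. Motion is simulated as slow random
walks (translation steps SD 0.02 mm, rotation steps SD 4e-4 rad), WM/CSF as
random-phase sums of slow sinusoids, and all three are mixed into the ROI
signals at 0.1 of each node's SD — small enough to be removable, large
enough that skipping the cleaning stage visibly biases correlations. A
10-volume burn-in with inflated variance and a decaying offset emulates the
unstable initial signal that the discard step removes.

The simulated tremor score is `score_scale * (b_s / hub_boost)` plus
Gaussian noise, truncated at zero, where `b_s` is the subject's realized
hub increment; unaffected groups score exactly zero. The noise SD (default
2, with `score_scale` 5 — UPDRS-like units) was calibrated once so that the
expected partial correlation between density-averaged hub centrality and
the score in the affected group is about 0.5, matching the magnitude of
effects this kind of study reports; the correlation stage therefore has a
recoverable target of realistic size. Ages are uniform on 45–70 years and
sex is Bernoulli(0.5), independent of the effect by default; a
`confound_age_sex` switch couples age to the hub increment for testing
covariate adjustment.

What the generator does **not** emulate: hemodynamic autocorrelation,
scanner drift spectra, spatial smoothness, or voxel-level structure. One
practical consequence: because the signals are temporally white, band-pass
filtering to 0.01–0.08 Hz cuts the effective degrees of freedom roughly to
the band fraction, so per-subject connectivity estimates are noisier
relative to the planted subject-level coupling spread than in real BOLD
data (where the spectrum already concentrates in the band). Recovery tests
on the graph-metric side are unaffected (the planted group shift is large),
but single-edge quantities such as the seed-beta clinical correlation are
strongly attenuated in the full synthetic chain; the clinical-correlation
operation is therefore validated by direct planted-coupling simulation.
Passing tests demonstrate internal correctness and statistical calibration
of the pipeline, not performance on real fMRI noise.

## Numerical conventions and degenerate inputs

- Residuals orthogonal to the design to ~1e-10; rank-deficient designs drop
  pivoted columns with a warning naming them.
- `Z = 0` when a module's degree spread is zero; `P = 0` for isolated
  nodes; `Q = 0` for edgeless graphs (single-module partition, with a
  warning).
- Thresholding requires the requested edge count not to exceed the
  available pairs; the band-pass upper edge must stay below Nyquist
  (`1/(2 TR)`), with the error naming the Nyquist frequency.
- Permutation p-values use the add-one convention `(1 + #exceed) / (1 + B)`
  so they are never zero and the FWE-corrected value always dominates the
  uncorrected one.
- All randomized stages (generation, Louvain restarts, permutations) take
  explicit seeds; the pipeline derives per-stage, per-subject seeds from
  one master seed, so a configuration reproduces every number.

## Problem sizes used for validation

The test suite validates the metrics against brute-force definitional
implementations on 200 random graphs of up to 12 nodes, modular recovery on
100 planted-partition graphs (40 nodes, 4 modules, p_in = 0.8,
p_out = 0.05, adjusted Rand > 0.9), null calibration of the ANCOVA group
test on 500 simulated null cohorts and of the mask-FWE on 500 null
replicates, and planted-effect recovery on 100 replicate cohorts at a
reduced scale chosen for iteration speed (30 nodes, 7 densities, 3
restarts, hub boost 0.25, 20 subjects per group) — the planted effect is
large enough that power is insensitive to these reductions. The acceptance
script runs the complete pipeline once at the full default scale (92 nodes,
31 densities, 60 subjects), with 20 Louvain restarts for the demonstration
cohort since the maximal Q saturates well below the default 100 restarts on
graphs of this size.

## Known limitations

- Binary graphs only; weighted-network analysis is out of scope, and the
  partition of borderline nodes can differ between weighted and binary
  treatments.
- The betweenness ordered-pair convention and the unnormalized default
  matter only up to a constant factor within a study; compare across
  studies with the normalized option.
- The voxel-level framewise displacement of imaging pipelines is not
  reconstructable here; the scalar convention is reported instead.
- The repeated-measures ANCOVA treats density as a categorical
  within-subject factor; monotone trends across densities are not modeled
  explicitly.
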