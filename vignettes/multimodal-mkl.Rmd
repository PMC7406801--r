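---
title: "Multimodal neuroimaging fusion with EasyMKL: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal neuroimaging fusion with EasyMKL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromkl)
```

# The problem

Alzheimer's disease alters the brain along several partially independent
axes: grey-matter atrophy (structural MRI), glucose hypometabolism
(FDG-PET), amyloid accumulation (AV45-PET), white-matter microstructure
(diffusion MRI), resting-state dynamics (rs-fMRI) and genetic risk (the
APOE ε4 allele). No single axis separates diagnostic groups reliably —
especially not stable from converting mild cognitive impairment — which
motivates fusing them. `neuromkl` implements that fusion as multiple
kernel learning: one kernel per modality, combined with learned convex-ish
weights inside a maximum-margin classifier, plus the voxel-level feature
extraction and graph-theoretic group comparison that surround it.

Because the imaging data this kind of study uses is access-restricted, the
package ships a synthetic cohort generator whose outputs have the
statistical structure the downstream methods assume. All tests and the
acceptance script run on generated data; users with real per-subject ROI
tables, 4D NIfTI volumes or genotype CSVs can enter the pipeline at any
stage.

# The EasyMKL classifier

For training subjects with labels $y_i \in \{+1,-1\}$ and base kernels
$K_1,\dots,K_R$ (one per modality, cosine-normalized so
$K_r(x,x) = 1$), EasyMKL solves, for a fixed regularizer
$\lambda \in [0,1]$,

$$\max_{\eta:\ \lVert\eta\rVert_2 = 1}\ \min_{\gamma \in \Gamma}\
(1-\lambda)\, \gamma^\top \hat Y \Big(\sum_r \eta_r K_r\Big) \hat Y \gamma
+ \lambda \lVert\gamma\rVert_2^2,$$

where $\hat Y = \mathrm{diag}(y)$ and
$\Gamma = \{\gamma \ge 0 : \sum_{y_i=+1}\gamma_i = 1,\ \sum_{y_i=-1}\gamma_i = 1\}$
is the product of the two class probability simplices; any
$\gamma \in \Gamma$ is a pair of points in the convex hulls of the two
classes, and the quadratic form is the squared distance between them in
the fused feature space. We implement the published two-phase reduction
rather than a saddle-point solver:

1. solve the $\gamma$ problem on the prior-weighted sum kernel
   $\sum_r w_r K_r$ (prior weights $w$ default to uniform $1/R$, the
   fixed-weight convex combination of the fusion contract);
2. set $\eta_r \propto \gamma^\top \hat Y K_r \hat Y \gamma$ — each
   kernel's contribution to the squared margin — normalized to
   $\lVert\eta\rVert_2 = 1$; rebuild $K^* = \sum_r \eta_r w_r K_r$ and
   re-solve $\gamma$ once on $K^*$.

The re-solve can only decrease the inner objective (it is an argmin over
the same domain), a property the test suite asserts. The decision score of
a new sample $s$ is $\sum_i \gamma_i y_i K^*(x_i, s) + b$ with the
threshold $b$ placed midway between the two class scores
($b = -\tfrac12[s(\mu_+) + s(\mu_-)]$); a score of exactly zero is
assigned to the positive class (a documented, arbitrary tie rule).

## Solver

The $\gamma$ subproblem is a strictly convex QP for $\lambda > 0$ and
convex at $\lambda = 0$. It is solved by projected gradient on
$\Gamma$: fixed step $1/L$ with
$L = 2[(1-\lambda)\,\lambda_{\max}(\hat Y K \hat Y) + \lambda]$,
deterministic uniform initialization ($\gamma_i = 1/n_\pm$ within each
class), Euclidean projection onto each simplex by the sorting algorithm,
stopping when the objective changes by less than $10^{-7}$ or after
$10^4$ iterations. Everything is deterministic, so identical inputs give
identical models. On problems small enough to enumerate, the solver's
objective matches a dense grid search over $\Gamma$ to better than
$10^{-3}$ (asserted in the tests).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lam` | LOOCV over $0, 0.1, \dots, 1$ | margin-vs-uniformity trade-off; $\lambda = 1$ has the closed-form uniform $\gamma$ |
| kernel `family` | polynomial | `degree = 2`, `offset = 1`; the degree is a convention — the analysis only fixes "polynomial" |
| `weights` | uniform $1/R$ | fixed prior fusion weights; the learned $\eta$ acts multiplicatively on top |
| RBF-SVM grid | $C = 1..9$, $\gamma \in \{10^{-4},\dots,1,7\}$ | baseline comparison grid; ties resolve to smaller $C$, then smaller $\gamma$ |

Feature standardization (z-scoring) always uses training-set statistics;
the cross kernels for test subjects reuse those statistics and the
training self-similarities for normalization, so no test information can
leak into the fit. λ selection by leave-one-out cross-validation operates
on sub-matrices of the training kernels (ties go to the smallest λ).

# The synthetic cohort

`cohort_spec()` defaults are the study conditions the rest of the package
assumes: four groups (AD 33, MCIc 31, MCIs 30, HC 35; 129 subjects),
modality blocks of 384 (sMRI), 384 (FDG), 384 (AV45), 200 (rs-fMRI),
50 (DTI) and 2 (APOE) features — 1404 per subject.

Non-APOE features are Gaussian with unit residual SD and three additive
components per group:

* a **mean shift** of `effect_size` · `noise_sd` · severity on the
  modality's affected regions, with severity 0 (HC), 1/3 (MCIs),
  2/3 (MCIc), 1 (AD) — a monotone disease gradient. The default
  `effect_size = 1.0` is a convention, not an estimate: the study this
  design emulates never reports effect magnitudes on its real data.
  `affected_fraction` (default 0.2) sets how many regions carry signal;
  `overlap` (default 0.3) sets how much of the affected set is shared
  across modalities, making modality information complementary — the
  regime in which fusion helps.
* a **global latent factor** with group-specific loading ρ
  (`covariance_strength`, defaults HC 0.2 / MCIs 0.3 / MCIc 0.4 /
  AD 0.5). The factor draw is rescaled to exact unit sample variance, so
  the injected inter-regional correlation is ρ² by construction rather
  than in expectation only.
* **modular factors**: regions are assigned round-robin to four modules,
  each with its own factor at loading ρ/2 (capped so the variance budget
  stays positive). A single global factor produces equicorrelation, which
  has *no topology* — graphs thresholded from it are indistinguishable
  from noise graphs — so group differences in ρ would be invisible to
  transitivity or modularity. The modular component concentrates strong
  edges within modules, making group graphs differ in structure, which is
  what the permutation machinery is meant to detect.

APOE genotypes are pairs of allele codes from {2, 3, 4} (kept as two
numeric features, matching the 2-feature block), drawn from per-group
allele distributions with ε4 enriched in AD and MCIc (AD 0.40, MCIc 0.35,
MCIs 0.20, HC 0.14 — in line with reported ε4 frequencies in clinical
cohorts). Age and sex are drawn from group-typical distributions and used
*only* for stratified splitting, mirroring their role as matching
variables.

4D volumes: `generate_timeseries_volume()` produces AR(1) noise
(TR = 3 s, 140 time points by default) plus a sinusoid confined to a
configurable effect box (frequencies above Nyquist are rejected);
`generate_tensor_volume()` produces axially symmetric eigenvalue triples
whose noise-free FA equals the compartment target exactly (targets ≥ 1
are rejected — they require a zero eigenvalue).

**What the generator does not emulate:** anatomy, spatial autocorrelation
of real brains, scanner artifacts, registration error, site effects,
realistic atlas geometry, or heavy-tailed feature distributions. Passing
tests therefore demonstrate the *methods* behave as specified under their
own assumptions — not that any particular accuracy will be achieved on
real imaging data.

# Voxel measures and statistics: conventions

* **FA/MD**: the standard eigenvalue formulas; all-zero voxels get FA = 0
  by convention; negative eigenvalues are an error naming the voxel.
* **Preprocessing**: the first 10 volumes are dropped, the per-voxel
  linear trend removed in closed form, and band-passing uses an ideal
  frequency-domain mask (out-of-band DFT bins zeroed) — deterministic and
  exactly testable, unlike an IIR design. Spatial smoothing is separable
  Gaussian with σ = FWHM/(2√(2 ln 2)) per axis, kernel truncated at 3σ
  with edge renormalization.
* **ALFF/fALFF**: one-sided amplitude 2|Xₖ|/T with the DC bin excluded
  from both bands. The amplitude normalization is a convention that
  cancels in fALFF and in group contrasts. The full-band upper limit is
  min(0.25 Hz, Nyquist) — at TR = 3 s Nyquist ≈ 0.167 Hz, so the nominal
  0.25 Hz cannot be resolved; the effective band is recorded on the
  result. Zero-spectrum voxels get fALFF = 0 with a warning count.
* **ReHo**: Kendall's W over m ∈ {7, 19, 27} neighbor series, average
  ranks on ties, no tie correction (the convention of the standard
  resting-state toolchain). Boundary voxels with incomplete neighborhoods
  are set to 0 and excluded via the returned interior mask — keeping m
  constant, as the formula assumes — rather than shrinking the
  neighborhood. ReHo is computed on unsmoothed detrended data by default;
  smoothing first is the user's choice via `preprocess_timeseries()`.
* **Group contrasts**: pooled-variance t by default (a Welch flag is
  provided), two-tailed p, `p_voxel ≤ 0.001` and an independent
  FDR (Benjamini–Hochberg) or FWER (Bonferroni) gate at α = 0.05 — the
  two corrections are exposed as independent gates because their
  precedence in standard SPM output tables is not recoverable. FWER is
  Bonferroni, not random-field theory (deterministic and conservative;
  RFT is out of scope). Zero-variance voxels are excluded with a count.
  Cluster extraction uses 26-connectivity by default (configurable to
  6/18); maximal connectivity avoids fragmenting the compact synthetic
  signals used in tests.

# Brain graphs: conventions

Structural connectivity is the Pearson correlation across subjects of
regional measures; functional connectivity is per-subject regional
correlation, Fisher-z averaged and back-transformed. Negative
correlations are set to zero and the diagonal is zero. Thresholding keeps
the E = round(d · n(n−1)/2) strongest edges (round half up; ties broken
by weight, then row, then column index, so the edge set is reproducible).

* **Characteristic path length** is the mean over ordered pairs with
  finite distance; disconnected pairs are excluded and counted (the only
  computable convention at low densities, where graphs fragment).
* **Transitivity** is implemented as the mean local clustering
  coefficient over all nodes (0 for degree < 2) — exactly the per-node
  formula used in this analysis tradition, which differs from the
  classical global triangle ratio.
* **Local efficiency** of node i is the mean inverse shortest-path length
  over ordered neighbor pairs *inside the neighbor-induced subgraph*,
  0 when degree < 2.
* **Modularity** Q = Σ_c (e_cc − a_c²) of the partition found by seeded
  Louvain maximization, best of 10 vertex-permuted restarts; Q, not the
  partition identity, is the reported output, and the trivial partition's
  Q = 0 is a lower bound. Shortest paths, subgraphs and Louvain come from
  `igraph`; all metric formulas are this package's own and are checked
  exactly against brute-force enumeration (Floyd–Warshall, triangle
  counting) on random graphs.

Group comparison permutes subject labels (subjects are the exchangeable
units), recomputing both networks and the measure per permutation;
p = (1 + #{|null| ≥ |obs|})/(n_perm + 1), with the 2.5/97.5 null
percentiles as the 95 % band. Failed permutations (e.g. a degenerate
graph) are redrawn and counted. For functional data the package averages
per-subject matrices into one group network; whether a per-subject or
group-level comparison is preferable is genuinely ambiguous in this
tradition, so the structural subject-permutation route is the one wired
into `permutation_group_test()`.

# Problem sizes in the test suite

The suite checks calibration and power claims on scaled problems chosen
to make the statistics sharp but the runtime modest: 200 null
permutation runs (15 + 15 subjects, 20 regions, 99 permutations) for the
type-I rate; 200 null voxel contrasts (5³ volumes, 8 + 8 subjects) for
the BH gate; 20 default-size cohorts (δ = 0.8, overlap 0.3) for the
fusion-benefit comparison with a coarsened λ grid (0, 0.25, …, 1); 100
two-kernel draws for the η-ranking property; 200 random graphs (n ≤ 20)
for exact brute-force agreement. These sizes are the package's choices
for a sharp-but-fast suite; the underlying functions default to the full
settings (1000 permutations, λ grid step 0.1, 41-density sweep).

# Known limitations

* The polynomial degree, RBF grid spacing and λ grid are conventions;
  the analysis tradition fixes only their families and ranges.
* Cluster-level inference is voxel-gated component extraction; no
  random-field or threshold-free cluster enhancement.
* No nuisance regression (motion, CSF/WM signals) — real-data
  preprocessing is assumed done upstream.
* Binary classification only; the multi-group setting is handled as six
  binary tasks.
* Graph metrics are for binary undirected graphs only; no weighted or
  directed variants.
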