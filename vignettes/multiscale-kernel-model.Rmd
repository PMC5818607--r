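---
title: "Predicting functional from structural connectivity with multi-scale diffusion kernels"
author: "diffusionMKL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting functional from structural connectivity with multi-scale diffusion kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffusionMKL)
```

## The model

Resting-state functional connectivity (FC) — the matrix of Pearson
correlations between regional BOLD time series — is shaped by the anatomical
wiring of the brain, the structural connectome (SC) measured by diffusion
tractography. A useful reduced description of that shaping is heat diffusion
on the structural graph: activity injected at a region spreads along white
matter at a characteristic spatial scale, and the propagator at scale
$\gamma$ is the heat kernel of the graph Laplacian,

$$H(\gamma) = \Psi e^{-\Lambda \gamma} \Psi^{\top},$$

where $L = \Psi \Lambda \Psi^{\top}$ is the (symmetric normalized, by
default) Laplacian of the subject's SC. Single-kernel models posit FC
$\approx H(\gamma^{*})$ at one optimal scale. The model implemented here
generalises this: FC is a superposition of diffusion kernels at $m$ scales,
each post-multiplied by a scale-specific *co-activation matrix* $\pi_i$
encoding which region pairs launch correlated activity at that scale,

$$C_f = \sum_{i=1}^{m} H_i \, \pi_i .$$

The kernels $H_i$ are subject-specific (they derive from the subject's SC);
the co-activations are shared across the cohort and are the model's only
trained parameters. Writing the kernels of subject $s$ side by side,
$H^s = [H_1^s \cdots H_m^s]$ ($n \times mn$), and stacking the $\pi_i$
vertically into $\Pi$ ($mn \times n$), each column $\Pi^{j}$ solves an
independent penalised regression over the training cohort,

$$\min_{\Pi^{j}} \; \bigl\lVert X \Pi^{j} - Y_{j} \bigr\rVert^2
  + \lambda \lVert \Pi^{j} \rVert_1,$$

with $X$ the vertical stack of the $H^s$ and $Y_j$ the concatenated $j$-th
FC columns. The $\ell_1$ penalty keeps the number of co-activating region
pairs small. This is a LASSO with **no intercept and no column
standardization**: all kernels live on a common spectral footing
($H(0) = I$, $\operatorname{tr} H$ decreasing in $\gamma$), and rescaling
columns would silently reweight scales. The total training objective equals
the sum of the $n$ column objectives, so columns are solved independently
with identical results in any order.

Two comparison models are included. The single-diffusion-kernel baseline
(SDK) sweeps a scale grid per subject, takes the cohort mode of the
per-subject optima, and predicts FC as the kernel at that scale. The
dynamic-mean-field baseline (DMF) integrates coupled stochastic gating
equations on the SC,
$\dot S_i = -S_i/\tau_S + (1 - S_i)\,\gamma H(x_i) + \sigma \nu_i$ with
$x_i = w J_N S_i + G J_N \sum_j C_{ij} S_j + I_0$, converts the gating
trajectory to BOLD through a Balloon–Windkessel model, and fits the single
global coupling $G$ per subject by sweeping $[0, 3]$.

## Parameters that matter

* **`m` (scales, default 16; synthetic studies use 4).** More scales give a
  richer dictionary but a more collinear design. The count is chosen
  empirically, not optimised.
* **Scale placement (`defaultScaleSet`).** Log-spaced between data-driven
  endpoints: $\gamma_{\min}$ where $\lVert H - I\rVert_F$ first reaches
  $0.01\,n$ and $\gamma_{\max}$ where $\lVert H - \Psi_0\Psi_0^{\top}
  \rVert_F$ falls to $0.01\,n$. Both deviations are closed-form functions of
  the eigenvalues, solved by bisection, so the endpoints are deterministic
  and independent of `m` (doubling `m` nests the extremes). The dictionary
  thus spans near-identity to near-stationarity; note the identifiability
  consequences below.
* **$\lambda$ (L1 penalty, `"auto"` by default).** Selected on the grid
  $\lambda_{\max} \cdot 10^{\{0,-0.5,\dots,-4\}}$ (where $\lambda_{\max}$
  zeroes every column) by 3-fold cross-validated prediction error over
  training subjects, with folds derived deterministically from the seed.
  Ties prefer the sparser model. The chosen value is recorded on the fitted
  object and serialized with it.
* **Laplacian normalization.** Symmetric normalized by default (spectra of
  all graphs then share $[0, 2]$, making scales comparable across subjects);
  the combinatorial form `unnormalized` is available.
* **DMF constants.** $a = 270$ nC$^{-1}$, $b = 108$ Hz, $d = 0.154$ s,
  $\gamma = 0.641$, $\tau_S = 0.1$ s, $w = 0.9$, $J_N = 0.2609$ nA,
  $I_0 = 0.3$ nA, noise $\sigma = 0.001$ nA — the standard reduced
  one-population values; hemodynamics use $\kappa = 0.65$ s$^{-1}$,
  $\gamma_h = 0.41$ s$^{-1}$, $\tau_h = 0.98$ s, $\alpha = 0.32$,
  $\rho = 0.34$, $V_0 = 0.02$. Integration is Euler–Maruyama at
  $dt = 1$ ms with the gating clipped to $[0, 1]$; SC is divided by its
  maximum entry before coupling so $G$ has a comparable range across
  cohorts (disable with `normalizeSC = FALSE`). Defaults simulate 500 s,
  discard a 20 s burn-in and sample every 2 s, i.e. an 8-minute window of
  240 BOLD samples.

## What the synthetic generator emulates — and what it does not

Real SC–FC cohorts of the kind this model targets are not redistributable,
so `generateCohort()` builds desk-scale stand-ins with known ground truth:
a modular weighted template (4 communities; within-module edges
lognormal(0, 0.5) at density 0.9, between-module lognormal(−2, 0.5) at
density 0.3 — heavy-tailed, rich-club-like weights), per-subject
multiplicative lognormal jitter, a sparse ground-truth $\Pi^{*}$ (5% of
entries nonzero; magnitudes uniform on $[0.5, 1.5]$ with random sign), and
FC from the forward model plus symmetric Gaussian noise, rescaled by one
cohort-wide scalar and given a unit diagonal so it satisfies FC invariants.

Two generator choices deserve justification:

* **Subject jitter sd 0.5.** Scale-specific co-activations are identified
  *only* through inter-subject variation: for a single subject the map
  $\{\pi_i\} \mapsto \sum_i H_i \pi_i$ has an $(m-1)n$-dimensional null
  space per column, and with near-identical subjects the stacked design is
  numerically rank-deficient. A jitter comparable to the template's own
  weight spread (both lognormal sd 0.5) is within the range of reported
  inter-subject variability of tractography weights and makes the recovery
  experiment well-posed.
* **Ground-truth magnitudes bounded away from zero.** A support-recovery
  benchmark needs a minimum effect size (the usual beta-min condition);
  entries arbitrarily close to zero are unrecoverable at any noise level
  and would make "the support" an ill-defined target.

Passing tests on these cohorts show that the estimator recovers what it is
mathematically entitled to recover under the forward model. They do **not**
show that real FC follows the forward model, that tractography biases are
survivable, or that the learned $\pi_i$ of a real cohort are
neuroscientifically meaningful.

One structural caveat matters when interpreting the robustness battery.
Because synthetic FCs are all generated from the *same* $\Pi^{*}$, the
cohort's FCs are strongly similar to one another, and the fitted model can
reproduce that shared component through the smallest-scale kernel, which is
within 1% (Frobenius) of the identity and therefore almost unchanged when
the SC weights are scrambled. Scrambling SC consequently degrades synthetic
predictions only slightly — the intact-vs-perturbed ordering holds and is
asserted, but the large margins seen on empirical cohorts (where FC
diversity is high and not itself model-generated) are not reproducible in
this synthetic world. The co-activation-side nulls (swapping $\pi_i$ across
scales, permuting the rows of $\Pi$) do destroy prediction here exactly as
on real data, because they corrupt the information carrier itself.

## Numerical choices

* Matrix exponentials are evaluated spectrally (exact for symmetric
  Laplacians), never by series; kernels are symmetrized after
  reconstruction to remove round-off asymmetry.
* Eigenvector signs are fixed (largest-magnitude entry positive) for
  reproducible serialization; all downstream kernels are provably invariant
  to the convention.
* The coordinate-descent LASSO works on the Gram matrix $X^{\top}X$, shared
  across all $n$ column problems, and declares convergence when the largest
  coordinate update in a sweep drops below `tol` (default $10^{-6}$);
  non-convergence returns the best iterate with a diagnostic warning.
  $\lambda = 0$ is solved exactly as the minimum-norm least-squares
  solution via the spectral pseudo-inverse, because coordinate descent
  crawls along the flat directions of this highly collinear design when
  nothing is penalised.
* Input SC matrices are symmetrized as $(W + W^{\top})/2$ and their
  diagonal zeroed before validation; asymmetry beyond $10^{-6}$ (relative)
  is an error rather than silently averaged. Isolated nodes are an error at
  construction (the normalized Laplacian is undefined) unless explicitly
  allowed, as when thresholding legitimately isolates a node — the result
  then carries a warning flag in its metadata.
* Tie-breaks are deterministic everywhere: scale sweeps and mode
  computations prefer the smaller scale, thresholding ranks ties
  lexicographically by (i, j), penalty selection prefers the sparser model.
* All randomness flows from one seed through named substreams
  (`subSeed(seed, stream)`), so fold splits, perturbation draws, simulator
  noise and cohort synthesis are independently reproducible; perturbation
  draws that would isolate a node are redrawn from a derived seed.
* Predicted FC is symmetrized by default — $\sum_i H_i \pi_i$ is not
  symmetric for general $\pi_i$ while empirical FC is — and every
  evaluation correlates off-diagonal upper-triangle entries only. Fitting,
  by contrast, targets the full FC matrix including its unit diagonal,
  matching the Frobenius training objective.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
cohorts of 15 subjects with 20 regions and 4 scales (robustness nulls use
250 draws), and integrate the mean-field model on 3–8 region graphs for
30–500 simulated seconds. These sizes exercise every code path while
keeping the complete suite in the minutes range; all operations accept
larger inputs unchanged.

## Known limitations

* The number of scales and their spacing are fixed before fitting, not
  estimated; the defaults are heuristics.
* Only undirected, nonnegative structural graphs are supported.
* Inverting the map (recovering SC from FC) is out of scope; the
  column-wise objective is convex in $\Pi$ but nothing constrains the
  recovered co-activations to be interpretable individually when kernels at
  neighbouring scales are nearly collinear.
* The DMF baseline is the reduced single-population variant without
  feedback inhibition control, and FC dynamics (time-varying FC) are not
  modelled.
* Interchange formats are plain delimited text plus JSON metadata; no HDF5
  container is provided.
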