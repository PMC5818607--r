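# diffusionMKL

Predicting resting-state **functional connectivity (FC)** from the
**structural connectome (SC)** by learning a sparse combination of
multi-scale graph diffusion kernels.

Whole-brain FC — the matrix of Pearson correlations between regional BOLD
time series — reflects, but is not identical to, the anatomical wiring
measured by diffusion tractography. This package implements a linear
structure–function model in which activity diffuses on the structural graph
at several spatial scales simultaneously. With `L = Ψ Λ Ψᵀ` the (symmetric
normalized) graph Laplacian of a subject's SC and
`H(γ) = Ψ exp(−Λγ) Ψᵀ` the heat kernel at diffusion scale γ, predicted FC is

```
C_f = Σᵢ Hᵢ πᵢ ,   i = 1 … m,
```

where the kernels `Hᵢ = H(γᵢ)` are subject-specific and the co-activation
matrices `πᵢ` (stacked into `Π`, mn × n) are shared across the cohort — the
model's only trained parameters. Each column of `Π` is estimated by a
column-wise LASSO over the training cohort,

```
min ‖X Πʲ − Yⱼ‖² + λ‖Πʲ‖₁ ,
```

with no intercept and no column standardization (X stacks the subjects'
kernel banks, Yⱼ the j-th FC columns). Two reference models are included for
comparison: the single-diffusion-kernel baseline (one kernel at the cohort's
modal optimal scale) and a reduced dynamic-mean-field simulator with a
Balloon–Windkessel BOLD stage and a global-coupling sweep. An evaluation
battery covers hold-out / leave-one-out / k-fold cross-validation, SC
thresholding, SC perturbation nulls, co-activation swap and row-permutation
nulls, and seed-based correlation maps. A synthetic cohort generator with
known sparse ground truth makes the whole pipeline testable without any
restricted clinical data.

## Worked example

```r
library(diffusionMKL)

# generate a 15-subject synthetic cohort with known ground truth
gen <- generateCohort(SyntheticCohortSpec(seed = 1L))
gen$cohort
#> SCFCCohort: 15 subjects, 20 regions, 4 scales

# fit the multiple-kernel model on 10 training subjects
stack <- fitMKL(gen$cohort[1:10], lambda = "auto", seed = 1L)
stack
#> CoactivationStack: 4 scales x 20 regions; lambda = 0.006113 ; sparsity = 0.614

# predict a held-out subject and score it
pred <- predictFC(gen$cohort@banks[[11]], stack)
fcCorrelation(pred, gen$cohort@fcs[[11]])
#> [1] 0.9973678

# cross-validate against the single-kernel baseline
crossValidate(gen$cohort, mklModelFactory(lambda = "auto"),
              protocol = "kfold", seed = 1L)
#> EvaluationReport (kfold): 15 subjects, mean r = 0.9975 (sd 0.0004098)
crossValidate(gen$cohort, sdkModelFactory(), protocol = "kfold", seed = 1L)
#> EvaluationReport (kfold): 15 subjects, mean r = 0.06284 (sd 0.02416)
```

The fitted object records the cross-validated penalty (λ ≈ 0.006) and the
achieved sparsity of `Π` (61% exact zeros here). On this multi-scale ground
truth the multiple-kernel model predicts held-out FC at r ≈ 0.997, while the
best single kernel — which can only reproduce one diffusion scale — reaches
r ≈ 0.06: with several scale-specific co-activation patterns in play, no
single kernel resembles the resulting FC.

Real data enter through delimited text matrices
(`readConnectome(path, type = "sc" | "fc")`, one file per subject,
`SCFCCohort(scs, fcs, m = 16)`), and fitted models serialize to a plain-text
directory (`writeMKLModel()` / `readMKLModel()`). A thin command-line
front end over the same functions ships in `inst/scripts/mkl-cli.R`
(subcommands `synth`, `fit`, `predict`, `sdk-fit`, `dmf-simulate`,
`evaluate`, `run`).

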