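# neuromkl

Multimodal classification of Alzheimer's disease (AD) and its prodromal
stages — converting and stable mild cognitive impairment (MCIc, MCIs) —
against healthy controls (HC), by fusing features from structural MRI,
FDG-PET, AV45-PET, resting-state fMRI and diffusion MRI together with the
APOE genotype. The package is aimed at neuroimaging methodologists who want
a tested, reproducible implementation of the whole analysis path, runnable
end to end on seeded synthetic cohorts (clinical multimodal imaging cohorts of this
kind are access-restricted, so every stage is exercised on data the
package generates itself).

## What it computes

**Voxel-level measures.** From diffusion-tensor eigenvalues
λ₁ ≥ λ₂ ≥ λ₃ ≥ 0:

    FA = sqrt(3/2) · sqrt(Σᵢ(λᵢ − ⟨λ⟩)² / Σᵢλᵢ²),   MD = ⟨λ⟩ = (λ₁+λ₂+λ₃)/3

From BOLD series (detrended, optionally band-passed with an ideal
frequency-domain mask): ALFF (mean one-sided Fourier amplitude over
0.01–0.08 Hz), fALFF (low-band amplitude as a fraction of the 0–0.25 Hz
total, capped at Nyquist) and ReHo (Kendall's coefficient of concordance W
over 7/19/27-voxel neighborhoods).

**Voxel statistics.** Pooled-variance two-sample t-maps, two-tailed p,
Benjamini–Hochberg or Bonferroni gates, connected-cluster extraction and
mask-mean "VOI" features.

**Kernel fusion and EasyMKL.** Per-modality blocks are z-scored with
training statistics, mapped through a polynomial kernel
k(x,y) = (xᵀy + c)^d, cosine-normalized
K(x,y) = k(x,y)/√(k(x,x)k(y,y)), and fused as K = Σₘ wₘ Kₘ with Σ wₘ = 1.
EasyMKL then solves, for a regularizer λ ∈ [0,1],

    min over γ ∈ Γ of (1 − λ) γᵀ Ŷ (Σᵣ ηᵣ wᵣ Kᵣ) Ŷ γ + λ‖γ‖²,

where Γ is the product of the positive- and negative-class probability
simplices and Ŷ = diag(y). Kernel weights ηᵣ ∝ γᵀŶKᵣŶγ (unit L2 norm) are
extracted from the sum-kernel solution and γ is re-solved on the fused
kernel; λ is chosen by leave-one-out cross-validation on the training set.
An RBF-SVM with a C/γ grid search is included as the single-kernel
baseline.

**Evaluation.** Sensitivity, specificity, precision, F1, balanced accuracy
(the mean of sensitivity and specificity), ROC/AUC (Mann–Whitney, ties ½)
and Cohen's kappa.

**Brain graphs.** Pearson connectivity (negatives zeroed), binary graphs
across a 5–25 % density sweep, characteristic path length, local
efficiency, transitivity (mean local clustering), Louvain modularity,
nodal degree, and subject-permutation group tests with 95 % null bands and
FDR-corrected nodal comparisons.

## Worked example

```r
library(neuromkl)

cohort <- generate_cohort(cohort_spec(seed = 1))   # 129 subjects, 1404 features
res <- run_mkl_pipeline(cohort, c("AD", "HC"), seed = 2)
print(res)
#> Multimodal MKL pipeline: AD vs HC (sMRI+FDG+AV45+rsfMRI+DTI+APOE)
#>   lambda = 0.00, test AUC = 0.9700, balanced ACC = 0.9000, kappa = 0.8000
#>   kernel weights (eta):
#>   sMRI    FDG   AV45 rsfMRI    DTI   APOE
#> 0.4628 0.4336 0.4396 0.4382 0.4505 0.0979
print(res$report)
#> Classification report (positive class: AD)
#>   TP=9 FP=1 TN=9 FN=1
#>   ACC(balanced)=0.9000  accuracy=0.9000  SEN=0.9000  SPEC=0.9000
#>   PRE=0.9000  F1=0.9000  kappa=0.8000
```

The pipeline generated a seeded synthetic cohort (33 AD / 31 MCIc /
30 MCIs / 35 HC; 384+384+384+200+50+2 features per subject), split AD vs
HC 70:30 with stratification, built one normalized polynomial kernel per
modality, selected λ by LOOCV, and scored the 20 held-out subjects: 18 of
20 correct, test AUC 0.97. The η vector shows the five imaging kernels
carrying similar weight and the 2-feature APOE kernel contributing least —
with complementary per-modality signal, the fused kernel beats each single
modality (compare `run_mkl_pipeline(..., modalities = "DTI")`).

A group graph comparison on the same cohort:

```r
ad <- cohort$blocks$sMRI[cohort$labels == "AD", ]
hc <- cohort$blocks$sMRI[cohort$labels == "HC", ]
permutation_group_test(ad, hc, "transitivity",
                       densities = seq(0.05, 0.25, 0.05), n_perm = 199, seed = 3)
#> Permutation test (transitivity, 199 permutations): 5/5 densities significant at 0.05
```

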