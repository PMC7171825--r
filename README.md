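# petmci

Predicting conversion from mild cognitive impairment (MCI) to Alzheimer's
disease from **longitudinal FDG-PET** scans and cognitive scores.

Clinicians and imaging researchers who follow MCI patients over repeat
¹⁸F-FDG-PET sessions want to know which patients will progress (pMCI) and
which will remain stable (sMCI). `petmci` implements a complete,
desk-testable version of a longitudinal classification framework for this
question: reference-cluster intensity normalization, atlas-based regional
features, dynamic change features, univariate F-score feature selection and
a leave-one-out RBF-SVM evaluation — together with a synthetic-cohort
generator that plants known group effects, so every stage can be validated
without access-controlled clinical data.

## The method

**Normalization (two steps).** Each PET volume is first scaled to unit
cerebral global mean. Because diseased brains are globally hypometabolic,
global-mean scaling makes their relatively *preserved* regions appear
hypermetabolic; a voxel-wise one-sided two-sample t-test of patients
against healthy controls (p < 0.05, patient mean higher) selects those
voxels as the **reference cluster**, and every image is rescaled by its
mean over that cluster (the Yakushev procedure). Clusters are recomputed
per timepoint.

**Features.** With T_i the mean normalized intensity of an atlas region at
timepoint i (baseline, m6, m12, m18), the package builds

- *static* features: T per region and timepoint (Static_mbl … Static_m18);
- *dynamic* features, for follow-up i = 1, 2, 3:

      D_i = T_baseline − T_i          (intensity difference)
      R_i = D_i / T_baseline          (change rate)

- *cognitive* features: MMSE and ADAS-cog at the four timepoints.

Age and gender are removed from imaging features by linear regression.

**Selection and classification.** Features are ranked by the F-score

    F(i) = [ (x̄ᵢ⁺ − x̄ᵢ)² + (x̄ᵢ⁻ − x̄ᵢ)² ] /
           [ (1/(n₊−1)) Σₖ (xₖᵢ⁺ − x̄ᵢ⁺)² + (1/(n₋−1)) Σₖ (xₖᵢ⁻ − x̄ᵢ⁻)² ]

and the top k enter a support vector machine with RBF kernel
K(x₁, x₂) = exp(−‖x₁ − x₂‖² / 2σ²). Evaluation is leave-one-out with
ranking, selection and scaling refit inside every training fold; pooled
held-out decision values yield ACC/SEN/SPE (pMCI positive), the ROC curve
and AUC.

## Worked example

```r
library(petmci)

cfg <- cohortConfig(nSmci = 20, nPmci = 15, nHc = 12, gridDims = c(8, 8, 6),
                    nRegions = 60, nAffectedRegions = 8, nReferenceRegions = 6)
run <- runPipeline(runConfig(cohort = cfg,
                             blocks = c("Static_mbl", "Static_m6", "Dynamic_1",
                                        "R1", "Cognitive", "Dynamic & Cognitive"),
                             k = 12L, seed = 7))
run$report
```

```
         feature_set  k    acc    sen spe    auc
          Static_mbl 12  37.14   6.67  60 0.3167
           Static_m6 12  94.29  93.33  95 0.9900
           Dynamic_1 12  85.71  73.33  95 0.8733
                  R1 12  85.71  73.33  95 0.8667
           Cognitive  8  91.43  86.67  95 0.9200
 Dynamic & Cognitive 12 100.00 100.00 100 1.0000
```

The simulated groups share their baseline intensity level and differ only
in decline *rate*, so baseline statics classify near chance (37% accuracy,
majority class is 57%) while any feature that sees a follow-up — Static_m6,
the difference D₁, the rate R₁, the falling cognitive scores — separates
the groups; combining dynamic and cognitive features is perfect on this
easy synthetic cohort. Individual results carry per-subject scores and the
ROC:

```r
run$results$Dynamic_1
#> CVResult: 35 LOO folds, k = 12 features/fold
#>   ACC 85.71%  SEN 73.33%  SPE 95.00%  AUC 0.8733
run$clusters$m6
#> ReferenceCluster: 37 voxels selected at alpha = 0.05
```

Baseline demographics of the simulated cohort, in the layout of a standard
Table 1 (chi-square for gender, pooled two-sample t otherwise):

```r
cohortStats(run$cohort@subjects)
#>  variable         test statistic df       p
#>    gender   chi-square    0.3804  1 0.53700
#>       age two-sample t   -0.5757 33 0.56900
#>   mmse_bl two-sample t    1.9413 33 0.06080
#>   adas_bl two-sample t   -3.3091 33 0.00227
```

`twoSampleTFromSummary()` and `chiSquare2x2()` also accept printed
mean ± SD / count summaries directly, for checking published demographic
tables without raw data.

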