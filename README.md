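# rectomics

Multiparametric-MRI radiomics prognostic modeling of 5-year overall
survival (OS) in stage II–III rectal cancer.

TNM staging alone is a blunt prognostic instrument for locally advanced
rectal cancer: patients at the same stage have very different long-term
outcomes. `rectomics` is for researchers who want to quantify how much
high-throughput imaging features add to conventional staging and
clinical-pathological factors. It implements the complete workflow —
image conditioning, a from-scratch 3D feature extraction engine, a
cross-validated LASSO signature, and a four-model comparison with
nomogram, calibration, and Kaplan–Meier outputs — plus a synthetic
multiparametric cohort generator so every stage runs and is tested
without any patient data.

## The model

Per patient, eight MRI channels (T1w, T2w, ADC, dynamic phases L2/L3/L4,
and subtraction images L3−L1, L4−L1) are z-score normalized, resampled to
1 mm isotropic spacing, the tumor mask is eroded by 1 mm, and intensities
are quantized to G = 64 gray levels per region. The extractor then emits
exactly

4,686 = 6 morphology + 8 × (14 histogram + 51 texture) + 8 × 520 wavelet

features: Galloway run-length features (SRE, LRE, GLN, RLN, RP, LGRE,
HGRE) and 22 Haralick-style co-occurrence features at distances d ∈ {1, 2}
averaged over the 13 unique 3D directions, on the native volume and on the
eight sub-bands (LLL … HHH) of a one-level 3D Haar transform.

Features pass a Spearman redundancy filter (|ρ| > 0.90) and an
L1-penalized logistic regression (4-fold CV × 100 repeats, binomial
deviance, fewer than 11 features by the 10:1 rule), giving the radiomics
score

    Rad_score = sigmoid(β₀ + Σᵢ βᵢ · featureᵢ),  sigmoid(x) = 1/(1+e^(−x))

with higher scores indicating better expected survival. Four logistic
risk models — TNM stage, clinical, Rad_score, combined — are compared by
rank-statistic AUC (bootstrap CI) and Harrell's C; the combined model gets
a Hosmer–Lemeshow calibration check and a 0–100-point nomogram; patients
are stratified at the Youden-optimal score cutoff and compared with the
log-rank test. The package also ships the fixed reference 8-term
signature (`reference_signature()`, intercept −0.664) resolved into the
extraction layout.

## Worked example

```r
library(rectomics)
report <- run_pipeline(cohort_config(n_patients = 60, seed = 1),
                       selection = selection_config(repeats = 10, seed = 1),
                       split_fraction = 0.7, boot = 200)
print(report)
#> <evaluation_report>
#>   signature: 10 terms, lambda 0.01152
#>   primary cohort (n=42): tnm AUC 0.61, clinical AUC 1.00, radiomics AUC 1.00, combined AUC 1.00
#>   test cohort (n=18): tnm AUC 0.64, clinical AUC 0.57, radiomics AUC 1.00, combined AUC 1.00
#>   HL p: primary 1.00, test 1.00; log-rank p: 1.5e-15 / 1.1e-06
```

The generator plants a texture/histogram difference between survivor and
non-survivor tumors, so the radiomics and combined models discriminate
essentially perfectly on the held-out cohort while TNM stage hovers near
chance and the overfit clinical model collapses out of sample (test AUC
0.57) — the qualitative pattern the method is designed to expose. The
log-rank p-values (1.5e-15 primary, 1.1e-06 test) show the Youden-split
risk groups separating in survival, and non-significant Hosmer–Lemeshow
p-values indicate no detectable miscalibration.

```r
glance(report)             # tibble: AUC, CI, C-index per model and cohort
tidy(report$signature)     # fitted signature terms
autoplot(report$km$primary)           # Kaplan-Meier risk strata
plot_calibration(report$hl$primary)   # calibration curve
plot_model_roc(report)                # four-model ROC overlay

rad_score(setNames(rep(0, 8), reference_signature()$terms$key),
          reference_signature())
#> [1] 0.3398416        # sigmoid(-0.664)

os_rate_by_stage()
#> # A tibble: 5 × 3
#>   stage     n os_rate_pct
#> 1 IIA      65        80
#> 2 IIB       3        66.7
#> 3 IIIA      9        77.8
#> 4 IIIB     68        75
#> 5 IIIC     20        55
```

See `vignettes/rectomics-methods.Rmd` for the full account of the model,
its numerical conventions, and the design decisions.

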