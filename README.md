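# mirtoo

MicroRNA-based tissue-of-origin (TOO) prediction for cancers of unknown
primary (CUP), built around absolute miRNA quantification by droplet digital
PCR (ddPCR).

A CUP presents as a metastasis whose primary site cannot be identified by
imaging, histology, or immunohistochemistry. Because metastatic cells retain
the miRNA expression program of their tissue of origin — and miRNAs survive
formalin fixation intact — a focused 89-assay ddPCR miRNA panel can be
profiled from any archival biopsy and used to infer the most probable
primary site. `mirtoo` implements that workflow for diagnostic
bioinformaticians and method developers:

- **Panel QC**: SNORD44-Ct-driven cDNA dilution rules (1:50 for Ct 24–30,
  1:100–1:200 below 24, repeat RT above 30) gating entry into ddPCR.
- **Preprocessing**: replicate averaging, per-sample 50th-percentile
  normalization over the 89 panel assays, `log2(x + 0.01)` features,
  exclusion of miR-122-5p (liver-microenvironment signal) and miR-21-5p
  (non-specific) leaving 87 prediction features, merging of the 19
  histological labels into 17 prediction classes (STAD-CRC, KICA),
  detectability filtering, and complete-linkage Manhattan clustering.
- **Two classifiers, from scratch**: nearest shrunken centroids with
  standardized deviations `d_kj = (x̄_kj − x̄_j) / (m_k (s_j + s_0))`
  soft-thresholded by Δ (default 0: a diagonal-covariance Gaussian
  discriminant using all 87 features), and an L1-penalized multinomial
  regression minimizing `(1/n)·NLL + λ Σ|β_kj|` (default λ = 0.019) by
  glmnet-style coordinate descent with a compiled inner loop and exact KKT
  conditions at the solution.
- **Call prioritization**: sex-compatibility filtering (no TGSC/PRAD in
  females, no OV/UCEC in males), top-two sites per model, and a
  two-criterion rule (probability > 0.80 in either model; else shared
  top-two membership with probability > 0.30; else the union of top-twos).
- **Evaluation**: stratified bootstrap out-of-bag error (N = 100),
  confusion matrices with positive prediction rate, top-two accuracy, and
  multi-metastasis concordance.
- **Survival screening**: per-miRNA ROC-optimal dichotomization,
  Kaplan–Meier/log-rank, and univariate Cox hazard ratios with 95% CI.
- **Synthetic ddPCR generator**: class-specific log-normal profiles,
  liver-site miR-122-5p inflation, patient-level replicate metastases, and
  expression-driven survival — fully seeded, so the entire pipeline is
  testable without any external data.

## Worked example

```r
library(mirtoo)

cfg <- sim_config(seed = 42)
profiles <- make_class_profiles(17, config = cfg)
ref <- simulate_reference_cohort(profiles, cfg)
ref$matrix
#> mir_matrix: 85 samples x 89 miRNAs [raw copies/uL]

feats <- log_transform(exclude_mirnas(normalize_median(ref$matrix)))
feats
#> mir_matrix: 85 samples x 87 miRNAs [normalized, log2]

nsc   <- fit_nsc(feats$values, ref$meta$class_label, delta = 0)
lasso <- fit_multinomial_lasso(feats$values, ref$meta$class_label,
                               lambda = 0.019)
nsc
#> nearest-shrunken-centroids model: 17 classes, 87/87 features used, delta = 0
lasso
#> multinomial lasso: 17 classes, 70/87 features with nonzero coefficients, lambda = 0.019

cups <- simulate_metastases(profiles, cfg, data.frame(
  patient_id = c("PT01", "PT01", "PT02"),
  origin     = c("CHOL", "CHOL", "LUAD"),
  site       = c("liver", "bone", "lymph node")))
mx <- log_transform(exclude_mirnas(normalize_median(cups$matrix)))
report <- predict_too(mx, cups$meta, nsc, lasso)
report[, c("sample_id", "top1_nsc", "p1_nsc", "top1_lasso", "p1_lasso",
           "rule", "final_sites")]
#>   sample_id top1_nsc    p1_nsc top1_lasso  p1_lasso rule final_sites
#> 1  PT01-M01     CHOL 0.9967096       CHOL 0.9532762    A        CHOL
#> 2  PT01-M02     CHOL 0.9994350       CHOL 0.3505354    A        CHOL
#> 3  PT02-M01     LUAD 0.9990195       LUAD 0.8223367    A        LUAD

bootstrap_error(feats$values, ref$meta$class_label, model = "nsc",
                n_boot = 100, seed = 42)
#> bootstrap (nsc, N = 100): overall error 0.6%
```

Reading the output: both metastases of patient PT01 — one of them a
liver-site biopsy whose miR-122-5p is inflated 50-fold by the
microenvironment — are called cholangiocarcinoma under rule A (a model
probability above 0.80), matching the hidden simulated origin; the
concordance of multi-site metastases from one patient is itself a useful
internal validation. The out-of-bag bootstrap error of 0.6% reflects the
well-separated synthetic cohort, not clinical performance.

A thin command-line surface over the same functions lives at
`inst/cli/mirtoo.R` (subcommands `simulate`, `qc`, `preprocess`, `train`,
`predict`, `evaluate`, `survival`), reading and writing TSV and versioned
JSON model files.

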