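# gmreserve

Grey-matter composite modelling of cognitive reserve and genetic risk
in familial frontotemporal dementia (FTD) cohorts.

## What this package is for

In families carrying autosomal-dominant FTD mutations (*GRN*, *MAPT*,
*C9orf72*), at-risk relatives can be imaged years before symptom
onset. A central question for trial design is which factors modulate
presymptomatic brain atrophy: mutation status itself, cognitive
reserve (proxied by years of education), and modifier genotypes such
as *TMEM106B* rs1990622 (C/T). `gmreserve` is for biostatisticians
and imaging researchers analysing such multicentre family cohorts. It
provides:

1. **Volume handling** — regional grey-matter volumes (6 cortical
   lobes, 7 subcortical structures per hemisphere, cerebellum)
   normalised to percent of total intracranial volume (TIV).
2. **A graph-regularised composite** — graph-Laplacian PCA (gLPCA)
   over an anatomical "skeleton" graph of the 27 measures. The fit
   minimises ‖X − UQᵀ‖²_F + α·tr(QᵀLQ) with orthonormal loadings Q and
   scores U = XQ, solved in closed form by the eigendecomposition of

       G_β = (1 − β)(I − XᵀX/λ_data) + β·L/λ_graph,

   taking the eigenvectors of the k smallest eigenvalues (β = 0 is
   classical PCA; β = 1 is graph-only). PC1 is the grey-matter
   composite.
3. **The interaction model** — a linear mixed-effects model fitted by
   ML with crossed random intercepts for pedigree and study site:

       PC1 ~ GS * Education * T + Age + Female + (1|pedigree) + (1|site)

   where GS ∈ {0,1} is carrier status and T ∈ {0,1,2} is the
   *TMEM106B* T-allele count; Wald z-tests per fixed effect, education
   slopes per GS × genotype cell (β₂ + β₄·GS + β₆·T + β₇·GS·T), and an
   allele-dose monotonicity verdict.
4. **Cohort statistics** — enrolment filter accounting, Pearson
   chi-square genotype comparisons, pooled-variance t-tests, a
   characteristics table by carrier status.
5. **A synthetic-cohort simulator** — family/site structure,
   Hardy–Weinberg genotypes, a latent outcome following the model
   above, and regional volumes that scale with head size — plus a
   parameter-recovery experiment validating the estimator against the
   generating truth.
6. **A reproducible pipeline** — `run_pipeline()` orchestrates
   simulate/load → filter → normalise → graph → gLPCA → mixed model →
   reports, writing every stage as plain text with a manifest;
   byte-identical under a fixed seed. A thin CLI lives at
   `inst/cli/gmreserve.R` (verbs `simulate`, `run`, `report`,
   `recover`).

## Worked example

Simulate a 231-subject cohort (77 families, 13 sites) under the
package's reference effect sizes, build the composite, and fit the
interaction model:

```r
library(gmreserve)

cfg    <- cohort_config(n_subjects = 231, missing_mri_prob = 0,
                        missing_genotype_prob = 0)
cohort <- generate_cohort(cfg, seed = 42)
truth  <- truth_params()
sim    <- generate_outcome_and_volumes(cohort, truth, seed = 43)

norm <- normalize_to_tiv(sim$volumes)
X    <- standardize(norm)
g    <- build_template_graph(default_parcellation())
m    <- fit_glpca(X, laplacian(g), k = 1, beta = 0.5)

cc <- component_correlations(m, X)
head(cc[order(cc$rank), c("measure", "r")], 3)
#>      measure         r
#> 1  frontal_l 0.6840263
#> 3 parietal_l 0.6599749
#> 7  frontal_r 0.6485845

scores <- data.frame(subject_id = m$subject_id, PC1 = m$U[, 1])
fit <- fit_lmm(build_design(cohort, scores))
fit
#> Linear mixed-effects interaction model (ML)
#> n = 231 subjects | 77 pedigrees | 13 sites
#>                   term estimate       se      z        p
#>            (Intercept)  2.85400 1.485000  1.923 5.45e-02
#>                     gs -2.16800 2.154000 -1.007 3.14e-01
#>              education -0.01056 0.099770 -0.106 9.16e-01
#>                   tmem  0.46960 0.910800  0.516 6.06e-01
#>         gs_x_education  0.08542 0.154100  0.554 5.79e-01
#>              gs_x_tmem  0.31780 1.557000  0.204 8.38e-01
#>       education_x_tmem -0.02509 0.064780 -0.387 6.98e-01
#>  gs_x_education_x_tmem  0.09753 0.110800  0.880 3.79e-01
#>                    age -0.06179 0.008556 -7.223 5.10e-13
#>                 female -0.72060 0.236000 -3.053 2.26e-03
#> Random effects (variance):
#>   pedigree (n = 77)  0 (SE 0)
#>   site     (n = 13)  0 (SE 0)
#>   residual           2.796
#> log-likelihood: -446.5176

slope_dose_monotonicity(fit)
#>  gs t_alleles     slope
#>   1         0 0.0748613
#>   1         1 0.1472948
#>   1         2 0.2197283
#> verdict: increasing in T-allele count
```

Reading the output: the composite's strongest correlates are frontal
and parietal measures (the regions given the largest generative
loadings); age and sex covariate effects are sharply estimated, while
single-cohort interaction estimates at n = 231 are noisy — their SEs
are wide under the uncentred coding — which is why validation averages
over replicate cohorts. The carrier education slope still increases
with T-allele count. PC1 is in standardised-composite units, so
coefficients are proportional, not equal, to the latent generative
values; `recover_parameters()` fits the latent outcome directly and
recovers them numerically:

```r
rec <- recover_parameters(cfg, truth, n_replicates = 50, seed = 1)
rec$summary[rec$summary$term %in%
            c("gs", "education", "gs_x_education_x_tmem"), ]
#>                   term  truth    mean   mc_se    z
#>                     gs -0.262 -0.2827 0.19700 -0.10
#>              education  0.035  0.0360 0.00895  0.11
#>  gs_x_education_x_tmem  0.110  0.1156 0.00953  0.59
```

An end-to-end run from a config file:

```r
run_pipeline(list(seed = 5,
                  synthetic = list(cohort = list(n_subjects = 231)),
                  glpca = list(k = 1, beta = 0.5)),
             out_dir = "run1")
make_report("run1")   # one-page plain-text summary
```

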