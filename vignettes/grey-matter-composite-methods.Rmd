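---
title: "Methods: a graph-regularised grey-matter composite and its interaction model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a graph-regularised grey-matter composite and its interaction model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmreserve)
```

## The scientific question

In families carrying autosomal-dominant frontotemporal dementia
mutations (*GRN*, *MAPT*, *C9orf72*), relatives at 50% risk can be
studied years before symptom onset. Two modifiers are of particular
interest: **cognitive reserve**, proxied by years of formal education,
and the ***TMEM106B*** rs1990622 C/T polymorphism, a known modifier of
FTD risk and onset. `gmreserve` implements a complete analysis chain
for asking whether mutation status (GS), education, and *TMEM106B*
genotype — individually and in interaction — modulate grey-matter
volume in such a cohort, and for validating that chain on synthetic
cohorts with a known generative truth.

The chain is: regional grey-matter volumes → percent of total
intracranial volume (TIV) → column standardisation → graph-Laplacian
PCA (gLPCA) over an anatomical "skeleton" graph → first principal
component score (the *grey-matter composite*) → linear mixed-effects
three-way interaction model with crossed random intercepts for
pedigree and study site.

## The mixed model

For subject $i$ in pedigree $f(i)$ enrolled at site $s(i)$, with
composite outcome $y_i$:

$$
y_i = \beta_0 + \beta_1\,\mathrm{GS}_i + \beta_2\,\mathrm{Edu}_i +
\beta_3\,T_i + \beta_4\,\mathrm{GS}_i\mathrm{Edu}_i +
\beta_5\,\mathrm{GS}_i T_i + \beta_6\,\mathrm{Edu}_i T_i +
\beta_7\,\mathrm{GS}_i\mathrm{Edu}_i T_i +
\beta_a\,\mathrm{Age}_i + \beta_s\,\mathrm{Fem}_i +
u_{f(i)} + v_{s(i)} + \varepsilon_i
$$

with $u_f \sim N(0, \sigma^2_{\mathrm{ped}})$,
$v_s \sim N(0, \sigma^2_{\mathrm{site}})$,
$\varepsilon_i \sim N(0, \sigma^2_e)$, all independent.

Coding decisions, fixed once and recorded in the fit metadata:

* **GS** is 0/1 (carrier of any of the three mutations = 1).
* ***TMEM106B*** enters as **T-allele count** $T \in \{0,1,2\}$
  (CC = 0, CT = 1, TT = 2). A single numeric coefficient per genotype
  term implies an additive allele coding, and under this coding the
  carrier education slope
  $\beta_2 + \beta_4 + T(\beta_6 + \beta_7)$ is steepest for TT and
  changes monotonically with allele count — the "dose-dependent"
  reading. A categorical coding cannot produce one coefficient per
  interaction and was rejected.
* **Education and age enter uncentred, in raw years.** No centring
  convention is assumed; the truth-recovery machinery uses the same
  coding, so estimates are internally consistent. Uncentred coding
  makes the GS main effect the carrier offset at zero years of
  education, and its standard error correspondingly large; this is a
  property of the parameterisation, not an estimation problem.
* **Sex** is coded female = 1.
* **Pedigree and site are crossed, not nested.** Families in a
  multicentre family study usually enrol at one centre, but the model
  must not rely on that; `lme4::lmer` handles crossed factors
  naturally.
* **Maximum likelihood** (not REML) is the default, with Wald
  $z = \hat\beta/\mathrm{SE}$ and two-sided normal p-values — the
  simplest internally consistent choice when interaction Wald tests
  are the quantity of interest. REML is available as a flag.
* Variance components are reported with approximate standard errors
  from a finite-difference Hessian of the profiled deviance (delta
  method to the variance scale, residual sigma held fixed). They are
  descriptive; no inference is built on them. A variance estimated on
  the boundary (zero) is a legitimate converged fit and is flagged via
  `singular`, not as non-convergence.

The optimiser is started at variance components of 0.1 on the outcome
scale, making fits deterministic given the data.

### Education slopes

`education_slope()` evaluates
$\partial y/\partial \mathrm{Edu} = \beta_2 + \beta_4\,\mathrm{gs} +
\beta_6\,t + \beta_7\,\mathrm{gs}\,t$, and
`slope_dose_monotonicity()` classifies the carrier slopes at
$t = 0, 1, 2$ as increasing / decreasing / constant / non-monotone
(differences below $10^{-12}$ count as flat).

## The grey-matter composite (gLPCA)

### Inputs

The default parcellation has 27 measures: 6 cortical lobes × 2
hemispheres, 7 subcortical structures × 2 hemispheres, and one
bilateral cerebellum. Volumes are first expressed as percent of TIV
(head-size removal), then **z-scored per measure**. Scaling is a
genuine design choice: the measures span two orders of magnitude
(accumbens ≈ 0.5 cm³, frontal lobe ≈ 75 cm³), and without unit
variance the graph penalty — which compares loadings of connected
measures — would be incommensurable across regions. The composite also
includes the cerebellum and excludes any whole-brain column; both are
configurable at the scheme level.

### The skeleton graph

Brain measures are spatially organised and strongly left-right
correlated, which plain PCA ignores. The package regularises the
loadings over an undirected graph with unit edges between:

* every left-right homologue pair;
* adjacent cortical lobes within a hemisphere (frontal–parietal,
  frontal–temporal, frontal–cingulate, frontal–insula,
  temporal–parietal, temporal–insula, temporal–occipital,
  parietal–occipital, parietal–cingulate, cingulate–insula);
* related subcortical structures within a hemisphere
  (hippocampus–amygdala, caudate–putamen, putamen–pallidum,
  putamen–accumbens, caudate–accumbens, thalamus–pallidum,
  hippocampus–thalamus);
* each subcortical structure and one cortical lobe of its hemisphere
  (medial-temporal structures → temporal; basal ganglia and
  thalamus → frontal);
* cerebellum ↔ both thalami.

This template is an anatomically motivated declaration, not an
estimate; analyses should report the graph used. Edges are unweighted
("skeleton"), weights being configurable. A data-driven alternative,
`build_correlation_graph()`, thresholds absolute Pearson correlations
at `tau`. The Laplacian is the combinatorial $L = D - W$.

### The fit

gLPCA minimises
$\lVert X - UQ^\top\rVert_F^2 + \alpha\,\mathrm{tr}(Q^\top L Q)$ over
orthonormal $Q$ with $U = XQ$. The closed-form solution diagonalises
the normalised composite operator

$$
G_\beta = (1-\beta)\left(I_p - \frac{X^\top X}{\lambda_{\mathrm{data}}}\right)
 + \beta\,\frac{L}{\lambda_{\mathrm{graph}}},
$$

taking $Q$ as the eigenvectors of the $k$ smallest eigenvalues
($\lambda_{\mathrm{data}}$, $\lambda_{\mathrm{graph}}$ are the largest
eigenvalues of $X^\top X$ and $L$; the penalty weight equivalence is
$\alpha = \beta\lambda_{\mathrm{data}} / ((1-\beta)\lambda_{\mathrm{graph}})$).
$\beta = 0$ is classical PCA; $\beta = 1$ uses the graph alone, whose
first component on a connected graph is the constant vector, i.e. a
plain average of standardised measures.

Numerical conventions:

* **Default $\beta = 0.5$**, a neutral midpoint between data and
  graph; no published value exists for this weight, so the pipeline
  exposes it and ships a sensitivity sweep over
  $\{0, 0.25, 0.5, 0.75, 0.9\}$ (`glpca_beta_sweep()`, and
  `beta_sweep` in the pipeline config). Conclusions should be stable
  across the sweep — in the packaged tests the sign of the carrier
  effect is.
* **Sign orientation:** each loading column is flipped so its sum over
  measures is ≥ 0 (fallback: first non-zero coordinate positive on an
  exactly balanced column). Higher PC1 therefore means larger overall
  grey matter, so carrier effects are expected negative and education
  effects positive.
* **Ties:** if the $k$-th and $(k+1)$-th eigenvalues are within
  $10^{-10}$ the fit warns and keeps deterministic index order.
* Components are reported alongside `component_correlations()`, the
  per-measure Pearson correlation with each score, ranked by $|r|$;
  this is the package's answer to "which regions drive the
  composite". Under the default synthetic truth (frontal, parietal,
  temporal loadings tripled) those lobes occupy the top ranks.

PC1 scores are in standardised-composite units: they are a weighted
sum of z-scored measures and are only *proportional* to any latent
volume scale, a point that matters for parameter recovery (below).

## The synthetic cohort generator

The generator exists so that every stage — and the chain end-to-end —
is testable without any data download. It emulates:

* **Family/site structure:** `n_families` families, sizes
  $1 + \mathrm{Poisson}(\mu - 1)$; when an exact cohort size is
  requested, the extra members beyond one per family are allocated
  multinomially, which is exactly the shifted-Poisson law conditioned
  on the total. Each family has one causal gene (proportions ≈
  GRN 43%, C9orf72 38%, MAPT 19% of families) and attends one site.
* **Genotypes:** carrier status is Bernoulli(0.5) per subject (the
  at-risk design); *TMEM106B* is Hardy–Weinberg with T-allele
  frequency 0.634, reproducing a CC/CT/TT mix near 11/51/37%.
  Genotypes are assigned per subject, not transmitted through the
  pedigree: the analyses under test assume genotype–GS independence,
  and a transmission model would add machinery without changing what
  is being validated.
* **Covariates:** education truncated-normal 13.8 ± 3.2 years on
  [5, 25], rounded to half-years; age truncated-normal 47 ± 13 on
  [19, 86]; 64% female; independent MRI (7.5%) and genotype (15.1%)
  missingness for the filter chain.
* **Latent outcome:** $g_i$ follows the mixed model above with
  reference fixed effects (GS −0.262, education 0.035, *TMEM106B*
  −0.035, GS×Edu −0.046, GS×T 0.055, Edu×T −0.0005, GS×Edu×T 0.110,
  age −0.052, female −0.527) and variance components
  $\sigma^2_{\mathrm{ped}} = 0.085$, $\sigma^2_{\mathrm{site}} = 0.004$.
  The intercept and residual variance have no published reference;
  the package sets $\beta_0 = 0$ and $\sigma^2_e = 0.911$ so that the
  three stochastic components sum to 1 (a unit latent noise scale).
  The alternative reading — unit *marginal* variance including fixed
  effects — is infeasible here: with uncentred covariates the fixed
  part alone has variance ≈ 1.4.
* **Volumes:** regional raw volume is
  $v_{ij} = (\mathrm{TIV}_i/\mathrm{TIV}_{\mathrm{ref}})
  (\mu_j + \lambda_j g_i + \eta_{ij})$ with plausible region means
  $\mu_j$ (e.g. frontal 75 cm³, accumbens 0.5 cm³), loadings
  $\lambda_j$ defaulting to 1.5% of $\mu_j$ per latent unit — tripled
  in frontal/parietal/temporal cortex — and noise $\eta$ with sd 3% of
  $\mu_j$ and correlation `lr_corr` (default 0.6) between left-right
  homologues. TIV is log-normal around 1.45 litres with a ±5.5%
  (log-scale) sex offset. Volumes scale *proportionally* with head
  size by construction: that is the empirical phenomenon percent-of-TIV
  normalisation exists to remove, and it means normalisation recovers
  $\mu_j + \lambda_j g_i + \eta_{ij}$ (over TIV~ref~) exactly. Had TIV
  been drawn independently of the volumes, the percent columns would
  carry a shared head-size factor that PC1 would latch onto, and the
  generator would be simulating an artefact the real pipeline does not
  have. With TIV variability set to zero the process reduces to
  $v_{ij} = \mu_j + \lambda_j g_i + \eta_{ij}$, the form used by the
  zero-noise identity tests.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: pedigree transmission of genotypes and
the resulting within-family genotype correlation; realistic
segmentation error (noise here is Gaussian and spatially structured
only through homologue pairs); per-gene differences in atrophy
topography; longitudinal change; informative missingness (flags are
independent of everything).

## Parameter recovery and test problem sizes

`recover_parameters()` simulates replicate cohorts (default 50, 231
subjects in 77 families across 13 sites), refits the ML model to each,
and compares mean estimates with the generating truth via Monte-Carlo
standard errors. Two choices deserve justification:

* **The recovery model is fitted to the latent score itself** (the
  generator returns it alongside the volumes). The estimator is then
  validated against an exactly known truth. Fitting to PC1 instead
  (`outcome = "pc1"`) exercises the whole chain, but PC1 is only
  proportional to the latent scale, so recovered coefficients are
  truth × an unidentified constant; that route checks signs, ordering
  and significance patterns, not numerical equality.
* **Replicate seeds are `seed`, `seed + 1`, …** so the experiment is
  one deterministic function of one seed.

Problem sizes used by the shipped tests, chosen to make the checks
sharp while keeping the default suite quick: 50 replicates × 231
subjects for recovery; 100 null replicates × 2,000 subjects for Wald
type-I calibration (per-term rejection counts compared with binomial
bounds around 5%); ~50,000 subjects for the variance-decomposition
invariant (±5%); ~5,000 for homologue-noise correlation checks
(|r| < 0.05 when `lr_corr` is 0); 2,000 for recovering homologue edges
with the correlation graph at `tau` = 0.5.

ML variance components at these group counts carry the usual small
downward bias and boundary truncation at 0; at the reference effect
sizes the pedigree-variance recovery stays within Monte-Carlo error of
truth, and the site variance (13 sites) is reported but too weakly
identified to test sharply.

## Degenerate inputs and numerical conventions

* Constant measure columns abort standardisation (named in the error);
  constant columns in the correlation graph correlate with nothing.
* Subjects with missing or non-positive TIV are dropped with a
  message; regional volumes must be positive and at most TIV (equality
  allowed as a boundary).
* A singular fixed-effect design errors, listing the aliased columns.
* Genotype strings outside CC/CT/TC/TT are rejected.
* Pearson chi-square requires a ≥ 2×2 integer table without zero
  margins and applies no continuity correction — with a correction the
  recomputable reference p-values (0.958, 0.419) are not reproduced.
* The two-group t-test uses the pooled-variance form; two identical
  constant groups return t = 0, p = 1, while unequal constant groups
  error (zero pooled variance).
* All file artefacts are plain delimited text or JSON; reruns of the
  pipeline under a fixed seed are byte-identical, which the tests
  assert by hashing artefacts.

## Known limitations

* The anatomical template graph is a declared approximation; no claim
  is made that it matches any particular published skeleton graph, and
  composite results should always be reported together with the graph
  used.
* Wald-on-ML inference ignores finite-sample df; with 77 pedigrees
  the normal reference is adequate, but small cohorts would warrant a
  df correction the package does not implement.
* Variance-component standard errors are delta-method approximations
  with sigma held fixed; near the boundary they degrade to NA/0.
* The generator's effect sizes produce a composite whose single-cohort
  interaction estimates are noisy at n = 231 (by design — that is the
  study condition being emulated); single-run significance should not
  be over-read, which is precisely why the recovery experiment
  averages over replicates.
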