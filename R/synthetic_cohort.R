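#' Configuration of a synthetic at-risk family cohort
#'
#' Describes a GENFI-like multicentre cohort of subjects at 50%
#' autosomal-dominant risk: families distributed over study sites, one
#' causal gene per family, Bernoulli(1/2) mutation carriership per
#' subject, Hardy-Weinberg TMEM106B rs1990622 genotypes, truncated-
#' normal education and age, and independent missingness flags for MRI
#' and genotype.  Defaults reproduce the reference cohort structure:
#' 77 families across 13 sites, 231 subjects, genotype mix from a
#' T-allele frequency of 0.634, education 13.8 +/- 3.2 years, 64%
#' female.
#'
#' @param n_families Number of families (>= 1).
#' @param mean_family_size Mean subjects per family (> 1 implies
#'   multi-member families); family size follows 1 + Poisson(mean - 1).
#' @param n_subjects Optional exact total cohort size.  When given,
#'   the per-family sizes are the shifted-Poisson draw conditioned on
#'   this total (equivalently: one subject per family plus a
#'   multinomial allocation of the remainder).  `NULL` leaves the total
#'   random.
#' @param n_sites Number of study sites; each family attends one site.
#' @param gene_mix Named proportions over `GRN`, `C9orf72`, `MAPT`
#'   summing to 1 (per family).
#' @param carrier_prob Per-subject probability of carrying the family
#'   mutation (autosomal-dominant at-risk design: 0.5).
#' @param t_allele_freq TMEM106B rs1990622 T-allele frequency.
#' @param education_mean,education_sd Years of schooling; draws are
#'   truncated to \[5, 25\] and rounded to half-years.
#' @param age_mean,age_sd,age_min,age_max Age distribution (years),
#'   truncated normal.
#' @param female_prob Probability of female sex.
#' @param missing_mri_prob,missing_genotype_prob Independent
#'   missingness probabilities for the two filter stages.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_families = 77,
                          mean_family_size = 3,
                          n_subjects = NULL,
                          n_sites = 13,
                          gene_mix = c(GRN = 33 / 77, C9orf72 = 29 / 77,
                                       MAPT = 15 / 77),
                          carrier_prob = 0.5,
                          t_allele_freq = 0.634,
                          education_mean = 13.8,
                          education_sd = 3.2,
                          age_mean = 47.2,
                          age_sd = 13,
                          age_min = 19,
                          age_max = 86,
                          female_prob = 0.64,
                          missing_mri_prob = 22 / 294,
                          missing_genotype_prob = 41 / 272) {
  cfg <- list(n_families = n_families, mean_family_size = mean_family_size,
              n_subjects = n_subjects, n_sites = n_sites,
              gene_mix = gene_mix, carrier_prob = carrier_prob,
              t_allele_freq = t_allele_freq,
              education_mean = education_mean, education_sd = education_sd,
              age_mean = age_mean, age_sd = age_sd,
              age_min = age_min, age_max = age_max,
              female_prob = female_prob,
              missing_mri_prob = missing_mri_prob,
              missing_genotype_prob = missing_genotype_prob)
  num <- cfg[setdiff(names(cfg), c("gene_mix", "n_subjects"))]
  for (f in names(num))
    if (!is.numeric(num[[f]]) || length(num[[f]]) != 1 ||
        !is.finite(num[[f]]))
      stop("cohort_config field '", f, "' must be a finite number")
  if (!is.null(n_subjects) &&
      (!is.numeric(n_subjects) || !is.finite(n_subjects) ||
         n_subjects < n_families))
    stop("cohort_config field 'n_subjects' must be >= n_families")
  if (n_families < 1) stop("cohort_config field 'n_families' must be >= 1")
  if (n_sites < 1) stop("cohort_config field 'n_sites' must be >= 1")
  if (mean_family_size < 1)
    stop("cohort_config field 'mean_family_size' must be >= 1")
  if (any(!is.finite(gene_mix)) || any(gene_mix < 0) ||
      abs(sum(gene_mix) - 1) > 1e-8)
    stop("cohort_config field 'gene_mix' must be proportions summing to 1")
  for (f in c("carrier_prob", "t_allele_freq", "female_prob",
              "missing_mri_prob", "missing_genotype_prob"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("cohort_config field '", f, "' must be a probability in [0, 1]")
  if (age_min >= age_max)
    stop("cohort_config field 'age_min' must be below 'age_max'")
  class(cfg) <- "cohort_config"
  cfg
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  x <- stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                                 stats::pnorm(hi, mean, sd)), mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort according to a [cohort_config()]: family sizes
#' (shifted Poisson, optionally conditioned on an exact total), one
#' gene and one site per family, per-subject carrier status, Hardy-
#' Weinberg TMEM106B genotype, truncated-normal education (rounded to
#' 0.5 years) and age, sex, and MRI/genotype availability flags.
#' Reproducible: the same config and seed give byte-identical tables.
#'
#' @param config A `cohort_config`.
#' @param seed Integer seed governing every draw.
#' @return Cohort data frame: `subject_id`, `family_id`, `site_id`,
#'   `gene`, `gs`, `tmem_genotype`, `tmem_t`, `education`, `age`,
#'   `sex`, `female`, `has_mri`, `has_genotype`.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "cohort_config"),
            is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), {
    nf <- as.integer(config$n_families)
    if (is.null(config$n_subjects)) {
      sizes <- 1L + stats::rpois(nf, config$mean_family_size - 1)
    } else {
      extra <- as.integer(config$n_subjects) - nf
      sizes <- 1L + as.integer(
        stats::rmultinom(1, extra, prob = rep(1, nf)))
    }
    n <- sum(sizes)
    family_id <- rep(sprintf("F%03d", seq_len(nf)), sizes)
    genes <- sample(names(config$gene_mix), nf, replace = TRUE,
                    prob = config$gene_mix)
    site_of_family <- sample(sprintf("site%02d", seq_len(config$n_sites)),
                             nf, replace = TRUE)
    gs <- stats::rbinom(n, 1, config$carrier_prob)
    tmem_t <- stats::rbinom(n, 2, config$t_allele_freq)
    education <- round(2 * rtruncnorm(n, config$education_mean,
                                      config$education_sd, 5, 25)) / 2
    age <- rtruncnorm(n, config$age_mean, config$age_sd,
                      config$age_min, config$age_max)
    female <- stats::rbinom(n, 1, config$female_prob)
    has_mri <- stats::runif(n) >= config$missing_mri_prob
    has_genotype <- stats::runif(n) >= config$missing_genotype_prob
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      family_id = family_id,
      site_id = rep(site_of_family, sizes),
      gene = rep(genes, sizes),
      gs = gs,
      tmem_genotype = c("CC", "CT", "TT")[tmem_t + 1],
      tmem_t = tmem_t,
      education = education,
      age = round(age, 1),
      sex = ifelse(female == 1, "female", "male"),
      female = female,
      has_mri = has_mri,
      has_genotype = has_genotype,
      stringsAsFactors = FALSE)
  })
}

default_region_means <- function(scheme) {
  base <- c(frontal = 75000, temporal = 55000, parietal = 50000,
            occipital = 35000, cingulate = 12000, insula = 7000,
            hippocampus = 3500, amygdala = 1500, caudate = 3500,
            putamen = 4500, accumbens = 500, pallidum = 1500,
            thalamus = 7000, cerebellum = 105000)
  mu <- base[scheme$structure]
  mu[is.na(mu)] <- 10000
  stats::setNames(as.numeric(mu), scheme$measure)
}

#' Generative truth for the synthetic outcome and volume process
#'
#' Holds every parameter of the latent grey-matter composite model —
#' the intercept, the seven interaction-model fixed effects (mutation
#' status GS, education, TMEM106B T-allele count, the three pairwise
#' products and the three-way product), the age and sex covariate
#' effects, the pedigree/site random-intercept variances and the
#' residual variance — plus the mapping from the latent score to
#' regional volumes: per-region means and loadings, per-region noise
#' scale, the left-right homologue noise correlation, and the
#' total-intracranial-volume (head-size) distribution.
#'
#' Fixed-effect and variance defaults are the package's reference
#' effect sizes for a presymptomatic FTD cohort; the intercept is 0 and
#' the residual variance 0.911, so pedigree + site + residual variance
#' is 1 (unit latent noise scale).
#'
#' @param scheme Parcellation scheme the loading profile refers to.
#' @param beta0 Latent intercept.
#' @param beta_gs,beta_edu,beta_tmem Main effects of mutation status,
#'   education (per year) and T-allele count.
#' @param beta_gs_edu,beta_gs_tmem,beta_edu_tmem Two-way interactions.
#' @param beta_gs_edu_tmem Three-way interaction.
#' @param beta_age,beta_sex Covariate effects (age per year; female = 1).
#' @param var_pedigree,var_site Random-intercept variances.
#' @param var_resid Residual variance of the latent score.
#' @param loading_profile Per-region effect of one latent unit on raw
#'   volume (mm^3); default 1.5% of the region mean, tripled for
#'   frontal, parietal and temporal cortex.
#' @param region_noise_sd Per-region residual volume sd (mm^3), scalar
#'   recycled or vector; default 3% of the region mean.
#' @param lr_corr Noise correlation between left-right homologue
#'   regions, in \[0, 1).
#' @param tiv_meanlog,tiv_sdlog Log-normal head-size distribution
#'   (mm^3); `tiv_sdlog = 0` gives every subject the reference TIV.
#' @param tiv_sex_shift Additive log-scale TIV shift: +shift for males,
#'   -shift for females.
#' @return A validated `truth_params` list.
#' @export
truth_params <- function(scheme = default_parcellation(),
                         beta0 = 0,
                         beta_gs = -0.262,
                         beta_edu = 0.035,
                         beta_tmem = -0.035,
                         beta_gs_edu = -0.046,
                         beta_gs_tmem = 0.055,
                         beta_edu_tmem = -0.0005,
                         beta_gs_edu_tmem = 0.110,
                         beta_age = -0.052,
                         beta_sex = -0.527,
                         var_pedigree = 0.085,
                         var_site = 0.004,
                         var_resid = 0.911,
                         loading_profile = NULL,
                         region_noise_sd = NULL,
                         lr_corr = 0.6,
                         tiv_meanlog = log(1.45e6),
                         tiv_sdlog = 0.04,
                         tiv_sex_shift = 0.055) {
  scheme <- validate_parcellation(scheme)
  mu <- default_region_means(scheme)
  if (is.null(loading_profile)) {
    w <- ifelse(scheme$structure %in% c("frontal", "parietal", "temporal"),
                3, 1)
    loading_profile <- 0.015 * mu * w / 3
  }
  if (is.null(region_noise_sd)) region_noise_sd <- 0.03 * mu
  p <- nrow(scheme)
  if (length(loading_profile) == 1)
    loading_profile <- rep(loading_profile, p)
  if (length(region_noise_sd) == 1)
    region_noise_sd <- rep(region_noise_sd, p)
  if (length(loading_profile) != p)
    stop("loading_profile must have one entry per region of the scheme")
  if (length(region_noise_sd) != p)
    stop("region_noise_sd must be scalar or one entry per region")
  tp <- list(scheme = scheme, region_means = mu,
             beta0 = beta0, beta_gs = beta_gs, beta_edu = beta_edu,
             beta_tmem = beta_tmem, beta_gs_edu = beta_gs_edu,
             beta_gs_tmem = beta_gs_tmem, beta_edu_tmem = beta_edu_tmem,
             beta_gs_edu_tmem = beta_gs_edu_tmem,
             beta_age = beta_age, beta_sex = beta_sex,
             var_pedigree = var_pedigree, var_site = var_site,
             var_resid = var_resid,
             loading_profile = stats::setNames(as.numeric(loading_profile),
                                               scheme$measure),
             region_noise_sd = stats::setNames(as.numeric(region_noise_sd),
                                               scheme$measure),
             lr_corr = lr_corr, tiv_meanlog = tiv_meanlog,
             tiv_sdlog = tiv_sdlog, tiv_sex_shift = tiv_sex_shift)
  for (f in c("var_pedigree", "var_site", "var_resid"))
    if (tp[[f]] < 0) stop("truth_params field '", f, "' must be >= 0")
  if (lr_corr < 0 || lr_corr >= 1)
    stop("truth_params field 'lr_corr' must be in [0, 1)")
  if (any(region_noise_sd < 0))
    stop("truth_params field 'region_noise_sd' must be >= 0")
  class(tp) <- "truth_params"
  tp
}

#' Latent fixed-effect predictor of a cohort under a generative truth
#'
#' @param cohort Cohort data frame.
#' @param truth A `truth_params`.
#' @return Numeric vector `beta0 + X beta` per subject (no random
#'   effects, no noise).
#' @keywords internal
latent_fixed_part <- function(cohort, truth) {
  with(cohort,
       truth$beta0 + truth$beta_gs * gs + truth$beta_edu * education +
         truth$beta_tmem * tmem_t + truth$beta_gs_edu * gs * education +
         truth$beta_gs_tmem * gs * tmem_t +
         truth$beta_edu_tmem * education * tmem_t +
         truth$beta_gs_edu_tmem * gs * education * tmem_t +
         truth$beta_age * age + truth$beta_sex * female)
}

#' Simulate the latent composite and the regional volume table
#'
#' The latent grey-matter score of subject *i* is
#' `g_i = beta0 + X_i beta + u_pedigree(family_i) + u_site(site_i) + e_i`
#' with independent normal random intercepts and residual.  Regional
#' raw volumes scale proportionally with the subject's head size:
#' `v_ij = (TIV_i / TIV_ref) * (mu_j + lambda_j * g_i + eta_ij)`,
#' where `eta` has per-region sd `region_noise_sd` and correlation
#' `lr_corr` between left-right homologues (0 elsewhere), and TIV is
#' log-normal with a sex offset.  Percent-of-TIV normalisation then
#' recovers `100 * (mu_j + lambda_j g_i + eta_ij) / TIV_ref` exactly,
#' which is what makes the normalisation step meaningful.
#'
#' @param cohort Cohort data frame from [generate_cohort()].
#' @param truth A `truth_params` for the cohort's parcellation scheme.
#' @param scheme Parcellation scheme (defaults to the truth's).
#' @param seed Integer seed.
#' @return List with `latent` (data frame `subject_id`, `latent`) and
#'   `volumes` (a `volume_table`).
#' @export
generate_outcome_and_volumes <- function(cohort, truth,
                                         scheme = truth$scheme, seed) {
  stopifnot(inherits(truth, "truth_params"), nrow(cohort) > 0)
  scheme <- validate_parcellation(scheme)
  if (!identical(scheme$measure, truth$scheme$measure))
    stop("truth_params loading profile does not match the scheme")
  p <- nrow(scheme)
  n <- nrow(cohort)
  withr::with_seed(as.integer(seed), {
    fams <- unique(cohort$family_id)
    sites <- unique(cohort$site_id)
    u_fam <- stats::setNames(
      stats::rnorm(length(fams), 0, sqrt(truth$var_pedigree)), fams)
    u_site <- stats::setNames(
      stats::rnorm(length(sites), 0, sqrt(truth$var_site)), sites)
    g <- latent_fixed_part(cohort, truth) +
      u_fam[cohort$family_id] + u_site[cohort$site_id] +
      stats::rnorm(n, 0, sqrt(truth$var_resid))
    g <- unname(g)

    # region noise: iid normal, then mix homologue pairs to lr_corr
    eta <- matrix(stats::rnorm(n * p), n, p,
                  dimnames = list(NULL, scheme$measure))
    rho <- truth$lr_corr
    if (rho > 0) {
      hp <- homologue_pairs(scheme)
      for (i in seq_len(nrow(hp))) {
        zl <- eta[, hp$left[i]]
        eta[, hp$right[i]] <- rho * zl +
          sqrt(1 - rho^2) * eta[, hp$right[i]]
      }
    }
    eta <- sweep(eta, 2, truth$region_noise_sd, "*")

    tiv <- exp(stats::rnorm(n, truth$tiv_meanlog +
                              ifelse(cohort$female == 1, -1, 1) *
                              truth$tiv_sex_shift,
                            truth$tiv_sdlog))
    tiv_ref <- exp(truth$tiv_meanlog)
    base <- matrix(truth$region_means, n, p, byrow = TRUE) +
      outer(g, truth$loading_profile) + eta
    if (any(base <= 0))
      stop("simulated volumes non-positive; reduce noise or loadings")
    vols <- sweep(base, 1, tiv / tiv_ref, "*")
    vt <- data.frame(subject_id = cohort$subject_id,
                     stringsAsFactors = FALSE)
    vt[scheme$measure] <- as.data.frame(vols)
    vt$tiv <- tiv
    list(latent = data.frame(subject_id = cohort$subject_id, latent = g,
                             stringsAsFactors = FALSE),
         volumes = volume_table(vt, scheme))
  })
}

#' Write a synthetic cohort to disk
#'
#' Cohort and volume tables go to CSV (UTF-8, header row, empty fields
#' for missing values); a JSON sidecar records the config, truth and
#' seed for reproducibility.
#'
#' @param cohort Cohort data frame.
#' @param volumes A `volume_table` (or `NULL`).
#' @param dir Output directory (created if absent).
#' @param config,truth,seed Provenance recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, volumes, dir, config = NULL,
                         truth = NULL, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8", na = "")
  if (!is.null(volumes))
    write_volume_table(volumes, file.path(dir, "volumes.csv"))
  sidecar <- list(seed = seed,
                  config = unclass(config),
                  truth = if (!is.null(truth)) {
                    tr <- unclass(truth); tr$scheme <- NULL; tr
                  })
  jsonlite::write_json(sidecar, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Parameter-recovery experiment for the interaction model
#'
#' Simulates `n_replicates` cohorts under a known truth, fits the ML
#' mixed model to each, and summarises the recovered fixed effects and
#' variance components against the generating values.  By default the
#' model is fitted to the latent composite itself, isolating the
#' estimator from the volume/gLPCA stages (set `outcome = "pc1"` to
#' run those too, noting that PC1 is only proportional to the latent
#' score).
#'
#' @param config A `cohort_config`; missingness is irrelevant here (the
#'   simulated cohorts are analysed in full).
#' @param truth A `truth_params`.
#' @param n_replicates Number of replicate cohorts.
#' @param seed Base seed; replicate r uses `seed + r - 1`.
#' @param outcome `"latent"` or `"pc1"`.
#' @param glpca_beta Mixing weight when `outcome = "pc1"`.
#' @return A `recovery_result`: list with `estimates` (replicate x term
#'   data frame), `summary` (term, truth, mean, mc_se, z), `n_replicates`.
#' @export
recover_parameters <- function(config, truth, n_replicates = 50,
                               seed = 1, outcome = c("latent", "pc1"),
                               glpca_beta = 0.5) {
  outcome <- match.arg(outcome)
  terms <- lmm_fixed_terms()
  truth_vec <- c(`(Intercept)` = truth$beta0, gs = truth$beta_gs,
                 education = truth$beta_edu, tmem = truth$beta_tmem,
                 gs_x_education = truth$beta_gs_edu,
                 gs_x_tmem = truth$beta_gs_tmem,
                 education_x_tmem = truth$beta_edu_tmem,
                 gs_x_education_x_tmem = truth$beta_gs_edu_tmem,
                 age = truth$beta_age, female = truth$beta_sex,
                 var_pedigree = truth$var_pedigree,
                 var_site = truth$var_site)
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    s <- as.integer(seed) + r - 1L
    cohort <- generate_cohort(config, seed = s)
    sim <- generate_outcome_and_volumes(cohort, truth, seed = s + 500000L)
    if (outcome == "latent") {
      scores <- sim$latent
      frame <- build_design(cohort, scores, outcome = "latent")
    } else {
      norm <- normalize_to_tiv(sim$volumes)
      X <- standardize(norm)
      graph <- build_template_graph(truth$scheme)
      model <- fit_glpca(X, laplacian(graph), k = 1, beta = glpca_beta)
      scores <- data.frame(subject_id = model$subject_id,
                           PC1 = model$U[, 1])
      frame <- build_design(cohort, scores, outcome = "PC1")
    }
    fit <- fit_lmm(frame)
    est <- stats::setNames(fit$fixed$estimate, fit$fixed$term)
    rows[[r]] <- c(est[names(truth_vec)[1:10]],
                   var_pedigree = fit$var_pedigree,
                   var_site = fit$var_site)
  }
  est <- as.data.frame(do.call(rbind, rows))
  means <- colMeans(est)
  mc_se <- apply(est, 2, stats::sd) / sqrt(n_replicates)
  summary <- data.frame(term = names(truth_vec),
                        truth = unname(truth_vec),
                        mean = unname(means[names(truth_vec)]),
                        mc_se = unname(mc_se[names(truth_vec)]),
                        stringsAsFactors = FALSE)
  summary$z <- (summary$mean - summary$truth) / summary$mc_se
  structure(list(estimates = est, summary = summary,
                 n_replicates = n_replicates, outcome = outcome),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("Parameter recovery over", x$n_replicates, "replicate cohorts (",
      x$outcome, "outcome )\n")
  s <- x$summary
  s$truth <- signif(s$truth, 4); s$mean <- signif(s$mean, 4)
  s$mc_se <- signif(s$mc_se, 3); s$z <- round(s$z, 2)
  print(s, row.names = FALSE)
  invisible(x)
}
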