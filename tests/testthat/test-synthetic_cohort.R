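test_that("cohort generation is seed-deterministic", {
  cfg <- cohort_config()
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c <- generate_cohort(cfg, seed = 6)
  expect_false(identical(a, c))
  truth <- truth_params()
  va <- generate_outcome_and_volumes(a, truth, seed = 9)
  vb <- generate_outcome_and_volumes(b, truth, seed = 9)
  expect_identical(va, vb)
})

test_that("cohort structure follows the configuration", {
  cfg <- cohort_config(n_subjects = 231)
  co <- generate_cohort(cfg, seed = 71)
  expect_equal(nrow(co), 231)
  expect_equal(length(unique(co$family_id)), 77)
  expect_lte(length(unique(co$site_id)), 13)
  # one gene and one site per family
  per_fam <- split(co, co$family_id)
  expect_true(all(vapply(per_fam, function(f)
    length(unique(f$gene)) == 1 && length(unique(f$site_id)) == 1,
    logical(1))))
  expect_true(all(co$education >= 5 & co$education <= 25))
  expect_true(all(co$education * 2 == round(co$education * 2)))
  expect_true(all(co$age >= cfg$age_min & co$age <= cfg$age_max))
  # degenerate carrier probability
  none <- generate_cohort(cohort_config(carrier_prob = 0), seed = 3)
  expect_true(all(none$gs == 0))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(cohort_config(education_sd = NaN), "education_sd")
  expect_error(cohort_config(carrier_prob = 1.4), "carrier_prob")
  expect_error(cohort_config(n_families = 0), "n_families")
  expect_error(cohort_config(age_min = 90, age_max = 80), "age_min")
  expect_error(cohort_config(gene_mix = c(GRN = 0.5, C9orf72 = 0.4,
                                          MAPT = 0.4)), "gene_mix")
  expect_error(cohort_config(n_subjects = 10, n_families = 77),
               "n_subjects")
})

test_that("genotype draws land near the reference cohort distribution", {
  cfg <- cohort_config(n_subjects = 231)
  # pooled over a few cohorts to damp binomial noise at n = 231
  pooled <- do.call(rbind, lapply(1:5, function(s)
    generate_cohort(cfg, seed = s)))
  prop <- prop.table(table(factor(pooled$tmem_genotype,
                                  levels = c("CC", "CT", "TT"))))
  expect_lt(abs(prop[["CC"]] - 0.114), 0.05)
  expect_lt(abs(prop[["CT"]] - 0.512), 0.05)
  expect_lt(abs(prop[["TT"]] - 0.374), 0.05)
})

test_that("genotypes satisfy Hardy-Weinberg proportions at large n", {
  q <- 0.634
  cfg <- cohort_config(n_families = 8000, mean_family_size = 3,
                       t_allele_freq = q)
  co <- generate_cohort(cfg, seed = 73)
  n <- nrow(co)
  prop <- prop.table(table(factor(co$tmem_t, levels = 0:2)))
  hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  for (i in 1:3)
    expect_lt(abs(prop[[i]] - hw[i]), 4 * sqrt(hw[i] * (1 - hw[i]) / n))
})

test_that("latent variance decomposes into pedigree + site + residual", {
  cfg <- cohort_config(n_families = 17000, mean_family_size = 3)
  truth <- truth_params(beta_gs = 0, beta_edu = 0, beta_tmem = 0,
                        beta_gs_edu = 0, beta_gs_tmem = 0,
                        beta_edu_tmem = 0, beta_gs_edu_tmem = 0,
                        beta_age = 0, beta_sex = 0)
  co <- generate_cohort(cfg, seed = 79)
  expect_gt(nrow(co), 45000)
  sim <- generate_outcome_and_volumes(co, truth, seed = 80)
  total <- truth$var_pedigree + truth$var_site + truth$var_resid
  expect_lt(abs(var(sim$latent$latent) / total - 1), 0.05)
})

test_that("left-right noise correlation tracks lr_corr", {
  base <- list(beta_gs = 0, beta_edu = 0, beta_tmem = 0, beta_gs_edu = 0,
               beta_gs_tmem = 0, beta_edu_tmem = 0, beta_gs_edu_tmem = 0,
               beta_age = 0, beta_sex = 0, var_pedigree = 0, var_site = 0,
               var_resid = 0, loading_profile = 0, tiv_sdlog = 0,
               tiv_sex_shift = 0)
  cfg <- cohort_config(n_families = 1700, mean_family_size = 3)
  co <- generate_cohort(cfg, seed = 83)
  expect_gt(nrow(co), 4500)
  for (rho in c(0, 0.6)) {
    truth <- do.call(truth_params, c(base, list(lr_corr = rho)))
    sim <- generate_outcome_and_volumes(co, truth, seed = 84)
    hp <- homologue_pairs(truth$scheme)
    r <- vapply(seq_len(nrow(hp)), function(i)
      cor(sim$volumes[[hp$left[i]]], sim$volumes[[hp$right[i]]]),
      numeric(1))
    if (rho == 0) expect_true(all(abs(r) < 0.05))
    else expect_true(all(abs(r - rho) < 0.08))
  }
})

test_that("truth parameters are validated against the scheme", {
  expect_error(truth_params(loading_profile = rep(1, 5)),
               "one entry per region")
  expect_error(truth_params(lr_corr = 1), "lr_corr")
  expect_error(truth_params(var_resid = -1), "var_resid")
  s <- small_sim(seed = 87)
  expect_error(
    generate_outcome_and_volumes(s$cohort, s$truth, scheme = pair_scheme(),
                                 seed = 1),
    "does not match")
})

test_that("cohort tables round-trip to disk with a metadata sidecar", {
  s <- small_sim(seed = 89, n_subjects = 40)
  dir <- withr::local_tempdir()
  write_cohort(s$cohort, s$volumes, dir, config = s$config,
               truth = s$truth, seed = 89)
  expect_true(all(file.exists(file.path(dir, c("cohort.csv", "volumes.csv",
                                               "metadata.json")))))
  back <- utils::read.csv(file.path(dir, "cohort.csv"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(back), 40)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  expect_equal(meta$seed, 89)
  expect_equal(meta$config$n_families, s$config$n_families)
  expect_equal(meta$truth$var_resid, s$truth$var_resid)
})
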