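test_that("TMEM106B genotypes code as T-allele counts", {
  expect_equal(tmem_allele_count(c("CC", "CT", "TT", "TC", NA)),
               c(0L, 1L, 2L, 1L, NA))
  expect_error(tmem_allele_count("GG"), "GG")
})

test_that("build_design lays out interaction columns and drops incomplete rows", {
  s <- small_sim(seed = 43)
  fr <- build_design(s$cohort, s$latent, outcome = "latent")
  expect_equal(nrow(fr), 231)
  expect_equal(attr(fr, "n_dropped"), 0L)
  # non-carrier rows have all GS-involving interaction columns at 0
  g0 <- fr[fr$gs == 0, ]
  expect_true(all(g0$gs_x_education == 0))
  expect_true(all(g0$gs_x_tmem == 0))
  expect_true(all(g0$gs_x_education_x_tmem == 0))
  # products match their factors
  expect_equal(fr$education_x_tmem, fr$education * fr$tmem)
  expect_equal(fr$gs_x_education_x_tmem, fr$gs * fr$education * fr$tmem)
  # missing education drops the subject, with accounting
  co2 <- s$cohort; co2$education[c(3, 9)] <- NA
  fr2 <- build_design(co2, s$latent, outcome = "latent")
  expect_equal(nrow(fr2), 229)
  expect_equal(attr(fr2, "n_dropped"), 2L)
  # genotype strings are validated
  co3 <- s$cohort; co3$tmem_t <- NULL; co3$tmem_genotype[5] <- "XY"
  expect_error(build_design(co3, s$latent, outcome = "latent"), "XY")
})

test_that("zero variance-component truth reproduces OLS fixed effects", {
  cfg <- cohort_config(n_subjects = 231, missing_mri_prob = 0,
                       missing_genotype_prob = 0)
  truth <- truth_params(var_pedigree = 0, var_site = 0)
  cohort <- generate_cohort(cfg, seed = 47)
  sim <- generate_outcome_and_volumes(cohort, truth, seed = 48)
  fr <- build_design(cohort, sim$latent, outcome = "latent")
  fit <- fit_lmm(fr)
  ols <- lm(outcome ~ gs + education + tmem + gs_x_education + gs_x_tmem +
              education_x_tmem + gs_x_education_x_tmem + age + female,
            data = fr)
  expect_equal(fit$fixed$estimate,
               unname(coef(ols)[fit$fixed$term]), tolerance = 1e-4)
  # nested-model likelihood: mixed fit can only improve on variance-0 fit
  expect_gte(fit$loglik, as.numeric(logLik(ols)) - 1e-6)
})

test_that("Wald columns are internally consistent", {
  s <- small_sim(seed = 53)
  fit <- fit_lmm(build_design(s$cohort, s$latent, outcome = "latent"))
  expect_true(all(abs(fit$fixed$z * fit$fixed$se - fit$fixed$estimate)
                  < 1e-8))
  expect_true(all(fit$fixed$p > 0 & fit$fixed$p <= 1))
  expect_equal(fit$fixed$p, 2 * pnorm(-abs(fit$fixed$z)))
  expect_true(fit$var_pedigree >= 0 && fit$var_site >= 0)
  expect_equal(fit$n, 231)
  expect_equal(fit$n_pedigrees, 77)
  expect_equal(fit$n_sites, 13)
})

test_that("singular designs fail loudly with the aliased column named", {
  s <- small_sim(seed = 59)
  fr <- build_design(s$cohort, s$latent, outcome = "latent")
  fr$age <- 2 * fr$education          # alias age to education
  expect_error(fit_lmm(fr), "aliased.*age|age.*aliased")
})

test_that("education slope follows the interaction arithmetic", {
  cf <- reference_coefs()
  expect_equal(education_slope(cf, gs = 1, t_alleles = 2),
               0.035 - 0.046 + 2 * (-0.0005 + 0.110))
  expect_equal(education_slope(cf, gs = 1, t_alleles = 0), 0.035 - 0.046)
  for (t in 0:2)
    expect_equal(education_slope(cf, gs = 0, t_alleles = t),
                 0.035 - 0.0005 * t)
  zero <- setNames(rep(0, length(cf)), names(cf))
  expect_equal(education_slope(zero, 1, 2), 0)
  expect_error(education_slope(cf, gs = 2, t_alleles = 1), "gs")
  expect_error(education_slope(cf, gs = 1, t_alleles = 3), "t_alleles")
})

test_that("slope dose report classifies monotonicity", {
  cf <- reference_coefs()
  rep1 <- slope_dose_monotonicity(cf, gs = 1)
  expect_equal(attr(rep1, "verdict"), "increasing")
  expect_equal(rep1$slope, c(-0.011, 0.0985, 0.208), tolerance = 1e-12)
  flat <- cf; flat["education_x_tmem"] <- 0; flat["gs_x_education_x_tmem"] <- 0
  expect_equal(attr(slope_dose_monotonicity(flat, gs = 1), "verdict"),
               "constant")
  flipped <- cf; flipped["gs_x_education_x_tmem"] <- -0.110
  expect_equal(attr(slope_dose_monotonicity(flipped, gs = 1), "verdict"),
               "decreasing")
})

test_that("fit export writes the Table-style fixed effects and metadata", {
  s <- small_sim(seed = 61)
  fit <- fit_lmm(build_design(s$cohort, s$latent, outcome = "latent"))
  fx <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_lmm_fit(fit, fx, js)
  back <- utils::read.csv(fx)
  expect_equal(back$term, fit$fixed$term)
  expect_equal(back$estimate, fit$fixed$estimate, tolerance = 1e-12)
  meta <- jsonlite::read_json(js)
  expect_equal(meta$n, 231)
  expect_equal(meta$var_pedigree, fit$var_pedigree, tolerance = 1e-12)
})
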