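# Shared fixtures, all built in code.

# Minimal two-measure scheme: one homologue pair.
pair_scheme <- function() {
  validate_parcellation(data.frame(
    measure = c("x_l", "x_r"),
    hemisphere = c("left", "right"),
    class = "cortical",
    structure = "x",
    stringsAsFactors = FALSE))
}

# Reference fixed-effect estimates of the interaction model, used for
# slope arithmetic without refitting anything.
reference_coefs <- function() {
  c(`(Intercept)` = 0, gs = -0.262, education = 0.035, tmem = -0.035,
    gs_x_education = -0.046, gs_x_tmem = 0.055,
    education_x_tmem = -0.0005, gs_x_education_x_tmem = 0.110,
    age = -0.052, female = -0.527)
}

# Small cohort + latent outcome + volumes under the default truth.
small_sim <- function(seed = 7, n_subjects = 231) {
  cfg <- cohort_config(n_families = min(77L, max(5L, n_subjects %/% 3L)),
                       n_subjects = n_subjects,
                       missing_mri_prob = 0, missing_genotype_prob = 0)
  truth <- truth_params()
  cohort <- generate_cohort(cfg, seed = seed)
  sim <- generate_outcome_and_volumes(cohort, truth, seed = seed + 1000L)
  list(config = cfg, truth = truth, cohort = cohort,
       latent = sim$latent, volumes = sim$volumes)
}

# Random connected-ish weighted graph on p nodes for property tests.
random_graph <- function(p, density = 0.4) {
  W <- matrix(0, p, p)
  idx <- which(upper.tri(W))
  on <- idx[stats::runif(length(idx)) < density]
  W[on] <- stats::runif(length(on), 0.2, 2)
  W <- W + t(W)
  region_graph(paste0("n", seq_len(p)), W)
}
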