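#' Build the three-way interaction model frame
#'
#' Merges a cohort table with composite scores and lays out the columns
#' of the interaction model: mutation status `gs` (0/1), `education`
#' (years, uncentred), `tmem` (TMEM106B rs1990622 T-allele count:
#' CC = 0, CT = 1, TT = 2), their three pairwise products, the
#' three-way product, and the fixed covariates `age` (years) and
#' `female` (1 = female).  Pedigree (family) and study site become the
#' two crossed random-intercept factors.  Subjects missing any field
#' are dropped and counted.
#'
#' @param cohort Data frame with `subject_id`, `family_id`, `site_id`,
#'   `gs`, `education`, `age`, and either `tmem_t` (0/1/2) or
#'   `tmem_genotype` (`"CC"`, `"CT"`/`"TC"`, `"TT"`), and either
#'   `female` (0/1) or `sex` (`"female"`/`"male"`).
#' @param scores Data frame with `subject_id` and the outcome column.
#' @param outcome Name of the outcome column in `scores`.
#' @return A `model_frame` data frame with attribute `n_dropped`.
#' @export
build_design <- function(cohort, scores, outcome = "PC1") {
  stopifnot(is.data.frame(cohort), is.data.frame(scores),
            outcome %in% names(scores))
  if (!"tmem_t" %in% names(cohort)) {
    if (!"tmem_genotype" %in% names(cohort))
      stop("cohort needs a tmem_t or tmem_genotype column")
    cohort$tmem_t <- tmem_allele_count(cohort$tmem_genotype)
  } else {
    bad <- !is.na(cohort$tmem_t) & !cohort$tmem_t %in% 0:2
    if (any(bad)) stop("tmem_t values outside {0, 1, 2}")
  }
  if (!"female" %in% names(cohort)) {
    if (!"sex" %in% names(cohort))
      stop("cohort needs a female or sex column")
    if (!all(cohort$sex %in% c("female", "male", NA)))
      stop("sex must be 'female' or 'male'")
    cohort$female <- as.integer(cohort$sex == "female")
  }
  if (!all(cohort$gs %in% c(0, 1, NA))) stop("gs must be 0 or 1")

  df <- merge(cohort[, c("subject_id", "family_id", "site_id", "gs",
                         "education", "tmem_t", "age", "female")],
              scores[, c("subject_id", outcome)],
              by = "subject_id", sort = FALSE)
  names(df)[names(df) == outcome] <- "outcome"
  names(df)[names(df) == "tmem_t"] <- "tmem"
  complete <- stats::complete.cases(
    df[, c("outcome", "gs", "education", "tmem", "age", "female",
           "family_id", "site_id")])
  n_dropped <- sum(!complete) + (nrow(cohort) - nrow(df))
  df <- df[complete, , drop = FALSE]
  df$gs_x_education <- df$gs * df$education
  df$gs_x_tmem <- df$gs * df$tmem
  df$education_x_tmem <- df$education * df$tmem
  df$gs_x_education_x_tmem <- df$gs * df$education * df$tmem
  df$pedigree <- factor(df$family_id)
  df$site <- factor(df$site_id)
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  class(df) <- c("model_frame", "data.frame")
  df
}

#' TMEM106B rs1990622 genotype to T-allele count
#'
#' @param genotype Character vector of `"CC"`, `"CT"` (or `"TC"`),
#'   `"TT"`; `NA` passes through.
#' @return Integer vector of T-allele counts 0/1/2.
#' @export
tmem_allele_count <- function(genotype) {
  g <- toupper(trimws(genotype))
  g[g == "TC"] <- "CT"
  bad <- !is.na(g) & !g %in% c("CC", "CT", "TT")
  if (any(bad))
    stop("unrecognised TMEM106B genotype(s): ",
         paste(unique(g[bad]), collapse = ", "))
  unname(c(CC = 0L, CT = 1L, TT = 2L)[g])
}

lmm_fixed_terms <- function() {
  c("gs", "education", "tmem", "gs_x_education", "gs_x_tmem",
    "education_x_tmem", "gs_x_education_x_tmem", "age", "female")
}

#' Fit the crossed-random-intercept interaction model
#'
#' Fits, by maximum likelihood (`REML = FALSE` by default), the linear
#' mixed model
#'
#'   `outcome ~ gs * education * tmem + age + female
#'             + (1 | pedigree) + (1 | site)`
#'
#' with pedigree and site as crossed (not nested) random intercepts.
#' Each fixed effect is reported with its Wald statistic
#' `z = estimate / SE` and two-sided normal p-value.  Variance
#' components get approximate standard errors from a finite-difference
#' Hessian of the profiled deviance (delta method on the variance
#' scale); these are descriptive only.
#'
#' @param frame A `model_frame` from [build_design()].
#' @param reml Use REML instead of ML (default `FALSE`).
#' @return An `lmm_fit`: list with `fixed` (term, estimate, se, z, p),
#'   `var_pedigree`, `var_site`, `var_resid`, `se_var_pedigree`,
#'   `se_var_site`, `loglik`, `converged`, `singular`, `n`,
#'   `n_pedigrees`, `n_sites`, `n_dropped`, `reml` and the underlying
#'   `merMod` as `fit`.
#' @export
fit_lmm <- function(frame, reml = FALSE) {
  stopifnot(is.data.frame(frame))
  terms <- lmm_fixed_terms()
  missing_cols <- setdiff(c("outcome", terms, "pedigree", "site"),
                          names(frame))
  if (length(missing_cols))
    stop("model frame is missing: ", paste(missing_cols, collapse = ", "))
  if (nlevels(droplevels(factor(frame$pedigree))) < 2 ||
      nlevels(droplevels(factor(frame$site))) < 2)
    stop("need at least 2 pedigrees and 2 sites")

  Xf <- as.matrix(cbind(`(Intercept)` = 1, frame[, terms]))
  qrX <- qr(Xf)
  if (qrX$rank < ncol(Xf)) {
    aliased <- colnames(Xf)[qrX$pivot[(qrX$rank + 1):ncol(Xf)]]
    stop("singular fixed-effect design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  fml <- stats::as.formula(paste(
    "outcome ~", paste(terms, collapse = " + "),
    "+ (1 | pedigree) + (1 | site)"))
  # start both random-intercept variances at 0.1 on the outcome scale
  sigma0 <- stats::sd(stats::lm.fit(Xf, frame$outcome)$residuals)
  start <- list(theta = rep(sqrt(0.1) / sigma0, 2))
  # singularity is reported through the `singular` flag, so silence
  # lme4's boundary-fit console message
  ctrl <- lme4::lmerControl(calc.derivs = TRUE,
                            check.conv.singular = "ignore")
  fit <- lme4::lmer(fml, data = frame, REML = reml, start = start,
                    control = ctrl)

  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- cf / se
  p <- 2 * stats::pnorm(-abs(z))
  fixed <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se), z = unname(z), p = unname(p),
                      stringsAsFactors = FALSE)

  vc <- as.data.frame(lme4::VarCorr(fit))
  var_of <- function(grp) vc$vcov[vc$grp == grp][1]
  var_pedigree <- var_of("pedigree")
  var_site <- var_of("site")
  var_resid <- var_of("Residual")
  se_vc <- varcomp_se(fit)

  # a boundary (singular) fit is a converged fit with a variance at 0;
  # only genuine optimizer trouble counts as non-convergence
  msgs <- fit@optinfo$conv$lme4$messages
  msgs <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  converged <- (is.null(msgs) || length(msgs) == 0) &&
    fit@optinfo$conv$opt == 0
  if (!converged)
    warning("mixed-model fit did not converge cleanly: ",
            paste(msgs, collapse = "; "))

  structure(list(
    fixed = fixed,
    var_pedigree = var_pedigree, var_site = var_site,
    var_resid = var_resid,
    se_var_pedigree = se_vc["pedigree"], se_var_site = se_vc["site"],
    loglik = as.numeric(stats::logLik(fit)),
    converged = converged,
    singular = lme4::isSingular(fit),
    n = nrow(frame),
    n_pedigrees = nlevels(droplevels(factor(frame$pedigree))),
    n_sites = nlevels(droplevels(factor(frame$site))),
    n_dropped = attr(frame, "n_dropped") %||% 0L,
    reml = reml, fit = fit), class = "lmm_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Approximate SEs of the two random-intercept variances: central-
# difference Hessian of the profiled deviance in theta, delta method to
# variance = sigma^2 * theta^2 (sigma held fixed).  NA when the Hessian
# is not invertible (e.g. a variance estimated on the boundary).
varcomp_se <- function(fit) {
  out <- c(pedigree = NA_real_, site = NA_real_)
  res <- tryCatch({
    dev <- stats::update(fit, devFunOnly = TRUE)
    th <- lme4::getME(fit, "theta")
    sg <- stats::sigma(fit)
    k <- length(th)
    h <- pmax(1e-4, abs(th) * 1e-4)
    H <- matrix(NA_real_, k, k)
    for (i in seq_len(k)) for (j in seq_len(i)) {
      ei <- ej <- rep(0, k); ei[i] <- h[i]; ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (dev(th + ei + ej) - dev(th + ei - ej) -
           dev(th - ei + ej) + dev(th - ei - ej)) / (4 * h[i] * h[j])
    }
    cov_theta <- 2 * solve(H)
    se_theta <- sqrt(pmax(diag(cov_theta), 0))
    se_var <- 2 * sg^2 * abs(th) * se_theta
    names(se_var) <- sub("\\.\\(Intercept\\)$", "", names(th))
    se_var
  }, error = function(e) NULL)
  if (!is.null(res)) out[names(out) %in% names(res)] <-
      res[intersect(names(out), names(res))]
  out
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed-effects interaction model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat("n =", x$n, "subjects |", x$n_pedigrees, "pedigrees |",
      x$n_sites, "sites",
      if (x$n_dropped > 0) paste("|", x$n_dropped, "dropped") else "", "\n")
  fx <- x$fixed
  fx$estimate <- signif(fx$estimate, 4)
  fx$se <- signif(fx$se, 4)
  fx$z <- round(fx$z, 3)
  fx$p <- signif(fx$p, 3)
  print(fx, row.names = FALSE)
  cat("Random effects (variance):\n")
  cat(sprintf("  pedigree (n = %d)  %.4g (SE %.3g)\n", x$n_pedigrees,
              x$var_pedigree, x$se_var_pedigree))
  cat(sprintf("  site     (n = %d)  %.4g (SE %.3g)\n", x$n_sites,
              x$var_site, x$se_var_site))
  cat(sprintf("  residual           %.4g\n", x$var_resid))
  cat("log-likelihood:", x$loglik,
      if (!x$converged) "(NOT converged)" else "", "\n")
  invisible(x)
}

coef_lookup <- function(fit) {
  if (inherits(fit, "lmm_fit")) {
    stats::setNames(fit$fixed$estimate, fit$fixed$term)
  } else if (is.numeric(fit) && !is.null(names(fit))) {
    fit
  } else stop("expected an lmm_fit or a named coefficient vector")
}

#' Education slope for a mutation-status / genotype cell
#'
#' The model-implied change in composite grey-matter volume per year of
#' education for a subject with mutation status `gs` and `t_alleles`
#' TMEM106B T alleles:
#'
#'   `slope = b_edu + b_gs:edu * gs + b_edu:tmem * t + b_gs:edu:tmem * gs * t`
#'
#' @param fit An `lmm_fit`, or a named coefficient vector containing
#'   `education`, `gs_x_education`, `education_x_tmem`,
#'   `gs_x_education_x_tmem`.
#' @param gs Mutation status, 0 or 1.
#' @param t_alleles T-allele count, 0, 1 or 2.
#' @return Slope in composite units per year of education.
#' @export
education_slope <- function(fit, gs, t_alleles) {
  if (!all(gs %in% c(0, 1))) stop("gs must be 0 or 1")
  if (!all(t_alleles %in% 0:2)) stop("t_alleles must be 0, 1 or 2")
  cf <- coef_lookup(fit)
  need <- c("education", "gs_x_education", "education_x_tmem",
            "gs_x_education_x_tmem")
  if (!all(need %in% names(cf)))
    stop("missing coefficient(s): ",
         paste(setdiff(need, names(cf)), collapse = ", "))
  unname(cf["education"] + cf["gs_x_education"] * gs +
           cf["education_x_tmem"] * t_alleles +
           cf["gs_x_education_x_tmem"] * gs * t_alleles)
}

#' Dose-dependence of the education slope across T-allele count
#'
#' Reports, for mutation carriers, the education slope at 0, 1 and 2
#' T alleles and whether the slopes are monotone in allele count —
#' the model's verdict on an allele-dose-dependent modulation of the
#' education effect.
#'
#' @param fit As in [education_slope()].
#' @param gs Mutation-status stratum to evaluate (default 1, carriers).
#' @param tol Differences below `tol` count as flat.
#' @return A `slope_dose_report`: data frame of slopes with attribute
#'   `verdict` in `"increasing"`, `"decreasing"`, `"constant"`,
#'   `"non-monotone"`.
#' @export
slope_dose_monotonicity <- function(fit, gs = 1, tol = 1e-12) {
  slopes <- vapply(0:2, function(t) education_slope(fit, gs, t), 0)
  d <- diff(slopes)
  verdict <- if (all(abs(d) <= tol)) "constant"
  else if (all(d > tol)) "increasing"
  else if (all(d < -tol)) "decreasing"
  else "non-monotone"
  out <- data.frame(gs = gs, t_alleles = 0:2, slope = slopes)
  attr(out, "verdict") <- verdict
  class(out) <- c("slope_dose_report", "data.frame")
  out
}

#' @export
print.slope_dose_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("verdict:", attr(x, "verdict"), "in T-allele count\n")
  invisible(x)
}

#' Export a fitted mixed model
#'
#' Writes the fixed-effects table as CSV (term, estimate, se, z, p) and
#' the variance components plus fit metadata as JSON.
#'
#' @param fit An `lmm_fit`.
#' @param fixed_path,json_path Output paths.
#' @export
write_lmm_fit <- function(fit, fixed_path, json_path) {
  utils::write.csv(fit$fixed, fixed_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(var_pedigree = fit$var_pedigree, var_site = fit$var_site,
         var_resid = fit$var_resid,
         se_var_pedigree = fit$se_var_pedigree,
         se_var_site = fit$se_var_site,
         loglik = fit$loglik, converged = fit$converged,
         singular = fit$singular, n = fit$n,
         n_pedigrees = fit$n_pedigrees, n_sites = fit$n_sites,
         n_dropped = fit$n_dropped, reml = fit$reml,
         coding = list(gs = "carrier=1", tmem = "T-allele count 0/1/2",
                       education = "raw years, uncentred",
                       age = "raw years, uncentred", female = "female=1")),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(fixed_path)
}
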