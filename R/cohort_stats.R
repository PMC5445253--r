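#' Apply the cohort filter chain with stage accounting
#'
#' Mirrors the enrolment flow of a multicentre at-risk cohort: subjects
#' without a usable MRI are removed first, then subjects without a
#' genotype, and each stage is accounted for so that
#' `final n = initial n - sum(removed)`.
#'
#' @param records Data frame with logical columns `has_mri` and
#'   `has_genotype`.
#' @return List with `report` (a `filter_report` data frame: `stage`,
#'   `n_entering`, `n_removed`, `reason`) and `retained` (the surviving
#'   records).
#' @examples
#' rec <- data.frame(has_mri = c(TRUE, TRUE, FALSE),
#'                   has_genotype = c(TRUE, FALSE, TRUE))
#' filter_cohort(rec)$report
#' @export
filter_cohort <- function(records) {
  stopifnot(is.data.frame(records))
  if (!all(c("has_mri", "has_genotype") %in% names(records)))
    stop("records need logical columns has_mri and has_genotype")
  if (!is.logical(records$has_mri) || !is.logical(records$has_genotype))
    stop("has_mri and has_genotype must be logical")
  if (anyNA(records$has_mri) || anyNA(records$has_genotype))
    stop("has_mri and has_genotype must not contain NA")

  n0 <- nrow(records)
  keep1 <- records[records$has_mri, , drop = FALSE]
  n1 <- nrow(keep1)
  keep2 <- keep1[keep1$has_genotype, , drop = FALSE]
  n2 <- nrow(keep2)
  report <- data.frame(
    stage = c("at_risk", "usable_mri", "genotyped"),
    n_entering = c(n0, n0, n1),
    n_removed = c(0L, n0 - n1, n1 - n2),
    reason = c("initial at-risk records",
               "no usable volumetric MRI",
               "genotype not available"),
    stringsAsFactors = FALSE)
  class(report) <- c("filter_report", "data.frame")
  list(report = report, retained = keep2)
}

#' @export
print.filter_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat("final n =", x$n_entering[1] - sum(x$n_removed), "\n")
  invisible(x)
}

#' Deterministic enrolment-flow fixture
#'
#' Builds a record table with a prescribed number of at-risk subjects,
#' of whom `n_no_mri` lack a usable MRI and, among the remainder,
#' `n_no_genotype` lack a genotype; `n_carriers` of the fully observed
#' records are mutation carriers.  Defaults reproduce the package's
#' reference cohort flow (294 at risk, 22 without MRI, 41 without
#' genotype, 231 analysed: 108 carriers / 123 non-carriers).
#'
#' @param n_at_risk,n_no_mri,n_no_genotype,n_carriers Counts.
#' @return Data frame with `subject_id`, `has_mri`, `has_genotype`, `gs`.
#' @export
flowchart_fixture <- function(n_at_risk = 294, n_no_mri = 22,
                              n_no_genotype = 41, n_carriers = 108) {
  stopifnot(n_no_mri + n_no_genotype <= n_at_risk,
            n_carriers <= n_at_risk - n_no_mri - n_no_genotype)
  n_complete <- n_at_risk - n_no_mri - n_no_genotype
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_at_risk)),
    has_mri = rep(c(FALSE, TRUE), c(n_no_mri, n_at_risk - n_no_mri)),
    has_genotype = rep(c(TRUE, FALSE, TRUE),
                       c(n_no_mri, n_no_genotype, n_complete)),
    stringsAsFactors = FALSE)
  df$gs <- NA_integer_
  complete_idx <- which(df$has_mri & df$has_genotype)
  df$gs[complete_idx] <- rep(c(1L, 0L),
                             c(n_carriers, n_complete - n_carriers))
  df
}

#' Pearson chi-square test of a contingency table
#'
#' Plain Pearson statistic `sum((O - E)^2 / E)` with
#' `E = row total * column total / grand total`,
#' `df = (r - 1)(c - 1)`, upper-tail chi-square p-value, and no
#' continuity correction.
#'
#' @param counts Matrix (at least 2 x 2) of non-negative integer counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' # genotype distribution in two groups
#' tab <- rbind(c(14, 63, 46), c(11, 56, 41))
#' pearson_chi2(tab)$p_value
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop("counts must be non-negative and finite")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  if (sum(counts) <= 0) stop("grand total must be positive")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column total: expected counts would be zero")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Two-group pooled-variance Student t-test
#'
#' @param values_a,values_b Numeric vectors, each with at least two
#'   observations.
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_group_t <- function(values_a, values_b) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  pooled <- ((length(values_a) - 1) * stats::var(values_a) +
               (length(values_b) - 1) * stats::var(values_b)) /
    (length(values_a) + length(values_b) - 2)
  if (pooled <= 0) {
    if (mean(values_a) == mean(values_b)) {
      # all values identical in both groups: no evidence of difference
      return(list(t = 0, df = length(values_a) + length(values_b) - 2,
                  p_value = 1, mean_a = mean(values_a),
                  mean_b = mean(values_b)))
    }
    stop("zero pooled variance")
  }
  ht <- stats::t.test(values_a, values_b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value),
       mean_a = mean(values_a), mean_b = mean(values_b))
}

#' Descriptive summary table by mutation status
#'
#' Per-variable group summaries in the style of a cohort
#' characteristics table: mean +/- sd with a pooled-variance t-test for
#' continuous variables, percent (n) with a Pearson chi-square test for
#' categorical ones, comparing carriers (`gs = 1`) against
#' non-carriers (`gs = 0`).
#'
#' @param cohort Cohort data frame with `gs`, `age`, `education`,
#'   `female` (or `sex`), `tmem_genotype` (or `tmem_t`).
#' @return Data frame `variable`, `gs0`, `gs1`, `test`, `p_value`.
#' @export
cohort_summary_table <- function(cohort) {
  stopifnot(is.data.frame(cohort), "gs" %in% names(cohort))
  if (!"female" %in% names(cohort) && "sex" %in% names(cohort))
    cohort$female <- as.integer(cohort$sex == "female")
  if (!"tmem_genotype" %in% names(cohort) && "tmem_t" %in% names(cohort))
    cohort$tmem_genotype <- c("CC", "CT", "TT")[cohort$tmem_t + 1]
  g0 <- cohort[cohort$gs == 0, ]
  g1 <- cohort[cohort$gs == 1, ]
  msd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  pct <- function(x) sprintf("%.1f (%d)", 100 * mean(x), sum(x))
  rows <- list()
  for (v in intersect(c("age", "education"), names(cohort))) {
    tt <- two_group_t(g0[[v]], g1[[v]])
    rows[[v]] <- data.frame(variable = v, gs0 = msd(g0[[v]]),
                            gs1 = msd(g1[[v]]), test = "t",
                            p_value = tt$p_value)
  }
  if ("female" %in% names(cohort)) {
    tab <- rbind(table(factor(g0$female, levels = 0:1)),
                 table(factor(g1$female, levels = 0:1)))
    rows$female <- data.frame(variable = "female", gs0 = pct(g0$female),
                              gs1 = pct(g1$female), test = "chi2",
                              p_value = pearson_chi2(tab)$p_value)
  }
  if ("tmem_genotype" %in% names(cohort)) {
    lv <- c("CC", "CT", "TT")
    tab <- rbind(table(factor(g0$tmem_genotype, levels = lv)),
                 table(factor(g1$tmem_genotype, levels = lv)))
    p <- pearson_chi2(tab)$p_value
    for (g in lv) {
      rows[[g]] <- data.frame(
        variable = paste0("tmem_", g),
        gs0 = pct(g0$tmem_genotype == g),
        gs1 = pct(g1$tmem_genotype == g),
        test = "chi2", p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
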