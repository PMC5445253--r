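test_that("standardize z-scores columns and inverts exactly", {
  V <- data.frame(subject_id = c("a", "b"), m1 = c(4, 6), m2 = c(10, 30))
  S <- standardize(V)
  # sd convention n - 1: sd(c(4, 6)) = sqrt(2), so z = ±1/sqrt(2)
  expect_equal(unname(S$X[, "m1"]), c(-1, 1) / sqrt(2))
  expect_equal(unname(S$X[, "m2"]), c(-1, 1) / sqrt(2))
  expect_equal(apply(S$X, 2, sd), c(m1 = 1, m2 = 1))
  withr::local_seed(5)
  V2 <- data.frame(subject_id = sprintf("s%d", 1:40),
                   a = rnorm(40, 100, 5), b = runif(40), c = rnorm(40))
  S2 <- standardize(V2)
  expect_true(all(abs(colMeans(S2$X)) < 1e-10))
  expect_true(all(abs(apply(S2$X, 2, sd) - 1) < 1e-8))
  expect_equal(destandardize(S2), V2, tolerance = 1e-12)
  V2$k <- 3
  expect_error(standardize(V2), "k")
})

test_that("beta = 0 reduces gLPCA to classical PCA (SVD oracle)", {
  withr::local_seed(101)
  n <- 60; p <- 8
  V <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(V) <- paste0("m", 1:p)
  V$subject_id <- sprintf("s%d", 1:n)
  S <- standardize(V)
  m <- fit_glpca(S, matrix(0, p, p), k = 3, beta = 0)
  sv <- svd(S$X)
  for (j in 1:3) {
    expect_gt(abs(cor(m$U[, j], S$X %*% sv$v[, j])), 1 - 1e-10)
    expect_equal(abs(sum(m$Q[, j] * sv$v[, j])), 1, tolerance = 1e-8)
  }
})

test_that("beta = 1 on a connected graph gives the constant loading", {
  s <- small_sim(seed = 13)
  S <- standardize(normalize_to_tiv(s$volumes))
  g <- build_template_graph(s$truth$scheme)
  m <- fit_glpca(S, laplacian(g), k = 1, beta = 1)
  p <- nrow(s$truth$scheme)
  expect_equal(unname(m$Q[, 1]), rep(1 / sqrt(p), p), tolerance = 1e-8)
  expect_equal(unname(m$U[, 1]), unname(rowSums(S$X) / sqrt(p)),
               tolerance = 1e-8)
})

test_that("small worked example matches a brute-force eigendecomposition", {
  # 4 x 3 data, path graph over 3 measures, beta = 0.5
  V <- data.frame(subject_id = c("a", "b", "c", "d"),
                  m1 = c(1, -1, 2, 0), m2 = c(0, 0, 1, -1),
                  m3 = c(-1, 1, -3, 1))
  S <- standardize(V)
  L <- rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1))
  m <- fit_glpca(S, L, k = 2, beta = 0.5)
  # oracle: direct dense construction of the composite operator
  XtX <- t(S$X) %*% S$X
  ld <- max(eigen(XtX, symmetric = TRUE)$values)
  lg <- max(eigen(L, symmetric = TRUE)$values)
  G <- 0.5 * (diag(3) - XtX / ld) + 0.5 * L / lg
  eg <- eigen(G, symmetric = TRUE)
  for (j in 1:2) {
    q_ref <- eg$vectors[, 3 + 1 - j]
    if (sum(q_ref) < 0) q_ref <- -q_ref
    expect_equal(unname(m$Q[, j]), unname(q_ref), tolerance = 1e-10)
    expect_equal(m$selected[j], eg$values[3 + 1 - j], tolerance = 1e-10)
  }
  expect_equal(m$U, S$X %*% m$Q)
})

test_that("returned loadings minimise the gLPCA objective over random candidates", {
  withr::local_seed(77)
  n <- 30; p <- 6
  V <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(V) <- paste0("m", 1:p)
  V$subject_id <- sprintf("s%d", 1:n)
  S <- standardize(V)
  g <- random_graph(p, density = 0.6)
  L <- laplacian(g)
  beta <- 0.6
  m <- fit_glpca(S, L, k = 1, beta = beta)
  alpha <- beta * m$lambda_data / ((1 - beta) * m$lambda_graph)
  objective <- function(q) {
    u <- S$X %*% q
    sum((S$X - u %*% t(q))^2) + alpha * drop(t(q) %*% L %*% q)
  }
  obj_fit <- objective(m$Q[, 1])
  for (i in 1:200) {
    q <- rnorm(p); q <- q / sqrt(sum(q^2))
    expect_gte(objective(q), obj_fit - 1e-8)
  }
})

test_that("PC1 is continuous in beta near 0 and scores are centred", {
  withr::local_seed(19)
  s <- small_sim(seed = 19)
  S <- standardize(normalize_to_tiv(s$volumes))
  L <- laplacian(build_template_graph(s$truth$scheme))
  m0 <- fit_glpca(S, L, k = 1, beta = 0)
  m1 <- fit_glpca(S, L, k = 1, beta = 0.01)
  angle <- acos(min(1, abs(sum(m0$Q[, 1] * m1$Q[, 1])))) * 180 / pi
  expect_lt(angle, 10)
  expect_lt(abs(mean(m1$U[, 1])), 1e-10)
})

test_that("gLPCA rejects invalid inputs", {
  s <- small_sim(seed = 23)
  S <- standardize(normalize_to_tiv(s$volumes))
  L <- laplacian(build_template_graph(s$truth$scheme))
  expect_error(fit_glpca(S, L, k = 1, beta = 1.2), "beta")
  expect_error(fit_glpca(S, L, k = 27, beta = 0.5), "k")
  expect_error(fit_glpca(S, L[1:5, 1:5], k = 1, beta = 0.5), "dimension")
  badL <- L; badL[1, 2] <- badL[1, 2] + 1
  expect_error(fit_glpca(S, badL, k = 1, beta = 0.5), "symmetric")
  expect_error(fit_glpca(S, matrix(0, 27, 27), k = 1, beta = 0.5),
               "empty graph")
})

test_that("component correlations equal the direct Pearson formula", {
  s <- small_sim(seed = 31)
  S <- standardize(normalize_to_tiv(s$volumes))
  L <- laplacian(build_template_graph(s$truth$scheme))
  m <- fit_glpca(S, L, k = 2, beta = 0.5)
  cc <- component_correlations(m, S)
  for (j in sample(27, 5))
    expect_equal(cc$r[cc$component == "PC1"][j],
                 cor(S$X[, j], m$U[, 1]), tolerance = 1e-12)
  expect_true(all(abs(cc$r) <= 1))
})

test_that("rank-1 noiseless data correlates perfectly with PC1", {
  withr::local_seed(3)
  u <- rnorm(40)
  load <- c(2, -1, 0.5, 3)
  V <- as.data.frame(outer(u, load) + 10)
  names(V) <- paste0("m", 1:4)
  V$subject_id <- sprintf("s%d", 1:40)
  S <- standardize(V)
  m <- fit_glpca(S, matrix(0, 4, 4), k = 1, beta = 0)
  cc <- component_correlations(m, S)
  expect_true(all(abs(abs(cc$r) - 1) < 1e-8))
})

test_that("highly loaded lobes dominate the PC1 correlation ranking", {
  # default truth triples frontal/parietal/temporal loadings
  s <- small_sim(seed = 37, n_subjects = 500)
  S <- standardize(normalize_to_tiv(s$volumes))
  L <- laplacian(build_template_graph(s$truth$scheme))
  m <- fit_glpca(S, L, k = 1, beta = 0.5)
  cc <- component_correlations(m, S)
  top3 <- cc$measure[cc$rank <= 3]
  lobes <- s$truth$scheme$structure[match(top3, s$truth$scheme$measure)]
  expect_true(all(lobes %in% c("frontal", "parietal", "temporal")))
})

test_that("beta sweep returns one model per weight", {
  s <- small_sim(seed = 41)
  S <- standardize(normalize_to_tiv(s$volumes))
  L <- laplacian(build_template_graph(s$truth$scheme))
  sweep <- glpca_beta_sweep(S, L, betas = c(0, 0.5, 0.9))
  expect_named(sweep, c("beta_0", "beta_0.5", "beta_0.9"))
  expect_s3_class(sweep$beta_0.9, "glpca_model")
})
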