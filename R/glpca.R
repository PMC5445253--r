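#' Column-standardise a normalised volume table
#'
#' Centres every measure column to mean 0 and scales it to unit standard
#' deviation (denominator `n - 1`).  The means and sds are stored so the
#' transform can be inverted.
#'
#' @param V A `normalized_volume_table`, or any data frame of numeric
#'   measure columns plus `subject_id`.
#' @return A `standardized_matrix`: list with `X` (n x p matrix),
#'   `subject_id`, `means`, `sds`.
#' @export
standardize <- function(V) {
  stopifnot(is.data.frame(V), nrow(V) >= 2)
  cols <- setdiff(names(V), "subject_id")
  M <- as.matrix(V[, cols, drop = FALSE])
  means <- colMeans(M)
  sds <- apply(M, 2, stats::sd)
  if (any(sds == 0))
    stop("constant measure column(s): ",
         paste(cols[sds == 0], collapse = ", "))
  X <- sweep(sweep(M, 2, means, "-"), 2, sds, "/")
  structure(list(X = X, subject_id = V$subject_id,
                 means = means, sds = sds),
            class = "standardized_matrix")
}

#' Invert [standardize()]
#'
#' @param S A `standardized_matrix`.
#' @return Data frame with `subject_id` and the de-standardised columns.
#' @export
destandardize <- function(S) {
  stopifnot(inherits(S, "standardized_matrix"))
  M <- sweep(sweep(S$X, 2, S$sds, "*"), 2, S$means, "+")
  out <- data.frame(subject_id = S$subject_id, stringsAsFactors = FALSE)
  out[colnames(M)] <- M
  out
}

# Orient each loading column so its sum over measures is >= 0; on an
# exactly balanced column fall back to making the first non-zero
# coordinate positive.
orient_loadings <- function(Q) {
  for (j in seq_len(ncol(Q))) {
    s <- sum(Q[, j])
    if (abs(s) < 1e-12) {
      nz <- which(abs(Q[, j]) > 1e-12)[1]
      s <- if (is.na(nz)) 1 else Q[nz, j]
    }
    if (s < 0) Q[, j] <- -Q[, j]
  }
  Q
}

#' Fit graph-Laplacian PCA
#'
#' Minimises the reconstruction error `||X - U Q'||_F^2` plus a graph
#' smoothness penalty `alpha * tr(Q' L Q)` over orthonormal loadings Q
#' with scores `U = X Q`.  The closed-form solution takes Q as the
#' eigenvectors belonging to the `k` smallest eigenvalues of the
#' normalised composite operator
#'
#'   `G_beta = (1 - beta) (I_p - X'X / lambda_data) + beta * L / lambda_graph`
#'
#' where `lambda_data` is the largest eigenvalue of `X'X` and
#' `lambda_graph` the largest eigenvalue of `L`; `beta` in \[0, 1\] mixes
#' data fidelity against graph smoothness (`beta = 0` is classical PCA,
#' `beta = 1` uses the graph alone).  The equivalent penalty weight is
#' `alpha = beta * lambda_data / ((1 - beta) * lambda_graph)`.
#'
#' @param X A `standardized_matrix`.
#' @param L Laplacian matrix (p x p, symmetric), e.g. from
#'   [build_template_graph()]; ignored when `beta = 0` (pass a zero
#'   matrix if no graph exists).
#' @param k Number of components (1 <= k < p).
#' @param beta Mixing weight in \[0, 1\].
#' @return A `glpca_model`: list with `beta`, `Q` (p x k orthonormal,
#'   sign-oriented), `U` (n x k scores), `eigenvalues` (all p, ascending
#'   selection order), `selected` (the k smallest), `lambda_data`,
#'   `lambda_graph`, `measures`, `subject_id`.
#' @examples
#' sch <- default_parcellation()
#' g <- build_template_graph(sch)
#' # see the vignette for a full cohort example
#' @export
fit_glpca <- function(X, L, k = 1, beta = 0.5) {
  stopifnot(inherits(X, "standardized_matrix"))
  p <- ncol(X$X)
  if (!is.numeric(beta) || length(beta) != 1 || beta < 0 || beta > 1)
    stop("beta must be a single value in [0, 1]")
  if (k >= p || k < 1) stop("k must satisfy 1 <= k < p")
  L <- as.matrix(L)
  if (nrow(L) != p || ncol(L) != p)
    stop("Laplacian dimension does not match the number of measures")
  if (max(abs(L - t(L))) > 1e-10) stop("Laplacian must be symmetric")

  XtX <- crossprod(X$X)
  lambda_data <- max(eigen(XtX, symmetric = TRUE, only.values = TRUE)$values)
  lambda_graph <- max(eigen(L, symmetric = TRUE, only.values = TRUE)$values)
  if (beta > 0 && lambda_graph <= 1e-12)
    stop("graph Laplacian is zero (empty graph); beta > 0 needs edges")

  G <- (1 - beta) * (diag(p) - XtX / lambda_data)
  if (beta > 0) G <- G + beta * L / lambda_graph
  eg <- eigen(G, symmetric = TRUE)
  vals <- rev(eg$values)               # ascending
  vecs <- eg$vectors[, p:1, drop = FALSE]
  if (p > k && abs(vals[k + 1] - vals[k]) < 1e-10)
    warning("eigenvalue tie at the component cut; keeping index order")
  Q <- orient_loadings(vecs[, seq_len(k), drop = FALSE])
  rownames(Q) <- colnames(X$X)
  colnames(Q) <- paste0("PC", seq_len(k))
  U <- X$X %*% Q
  structure(list(beta = beta, Q = Q, U = U,
                 eigenvalues = vals, selected = vals[seq_len(k)],
                 lambda_data = lambda_data, lambda_graph = lambda_graph,
                 measures = colnames(X$X), subject_id = X$subject_id),
            class = "glpca_model")
}

#' @export
print.glpca_model <- function(x, ...) {
  cat("graph-Laplacian PCA: beta =", x$beta, "|", ncol(x$Q),
      "component(s) over", length(x$measures), "measures\n")
  cat("smallest composite eigenvalues:",
      paste(signif(x$selected, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Correlations between PC scores and each grey-matter measure
#'
#' Bivariate Pearson correlations of every standardised measure column
#' with every component score, with a ranking by absolute correlation —
#' the package's account of which regions drive a component.
#'
#' @param model A `glpca_model`.
#' @param X The `standardized_matrix` the model was fitted to.
#' @return Data frame `measure`, `component`, `r`, `rank` (per
#'   component, 1 = largest `|r|`).  A zero-variance score column gives
#'   `NA` correlations.
#' @export
component_correlations <- function(model, X) {
  stopifnot(inherits(model, "glpca_model"),
            inherits(X, "standardized_matrix"))
  out <- NULL
  for (c in seq_len(ncol(model$U))) {
    u <- model$U[, c]
    if (stats::sd(u) == 0) {
      r <- rep(NA_real_, length(model$measures))
    } else {
      r <- as.vector(stats::cor(X$X, u))
    }
    block <- data.frame(measure = model$measures,
                        component = colnames(model$Q)[c],
                        r = r, stringsAsFactors = FALSE)
    block$rank <- rank(-abs(block$r), ties.method = "first",
                       na.last = "keep")
    out <- rbind(out, block)
  }
  rownames(out) <- NULL
  out
}

#' Sensitivity of a gLPCA + mixed-model analysis to the mixing weight
#'
#' Refits the composite and, through the supplied callback, anything
#' downstream for each `beta` in `betas`.
#'
#' @param X A `standardized_matrix`.
#' @param L Laplacian matrix.
#' @param betas Numeric vector of mixing weights.
#' @param k Components per fit.
#' @return Named list of `glpca_model`s, one per beta.
#' @export
glpca_beta_sweep <- function(X, L, betas = c(0, 0.25, 0.5, 0.75, 0.9),
                             k = 1) {
  fits <- lapply(betas, function(b) fit_glpca(X, L, k = k, beta = b))
  names(fits) <- paste0("beta_", betas)
  fits
}

#' Export a fitted gLPCA model
#'
#' Writes the model as JSON (beta, eigenvalues, loadings keyed by
#' measure name) and the subject scores as CSV.
#'
#' @param model A `glpca_model`.
#' @param json_path,scores_path Output file paths.
#' @export
write_glpca_model <- function(model, json_path, scores_path) {
  loadings <- as.data.frame(model$Q)
  loadings$measure <- rownames(model$Q)
  jsonlite::write_json(
    list(beta = model$beta,
         lambda_data = model$lambda_data,
         lambda_graph = model$lambda_graph,
         eigenvalues = model$eigenvalues,
         loadings = loadings[, c("measure",
                                 setdiff(names(loadings), "measure"))]),
    json_path, auto_unbox = TRUE, digits = NA)
  scores <- data.frame(subject_id = model$subject_id)
  scores[colnames(model$U)] <- model$U
  utils::write.csv(scores, scores_path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(json_path)
}
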