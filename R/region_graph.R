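#' Region graphs over grey-matter measures
#'
#' A region graph is an undirected, weighted graph whose nodes are the
#' measures of a parcellation scheme.  Its combinatorial Laplacian
#' `L = D - W` regularises the principal-component loadings in
#' [fit_glpca()], encoding the expectation that anatomically related
#' (and especially left-right homologous) measures carry similar
#' loadings.
#'
#' @param nodes Character vector of node (measure) names.
#' @param W Symmetric non-negative weight matrix with zero diagonal,
#'   `length(nodes)` square.
#' @return A `region_graph`: list with `nodes`, `W`, `degree` and
#'   `laplacian`.
#' @export
region_graph <- function(nodes, W) {
  W <- as.matrix(W)
  p <- length(nodes)
  stopifnot(is.character(nodes), nrow(W) == p, ncol(W) == p)
  if (anyDuplicated(nodes)) stop("duplicate node names")
  if (any(W < 0)) stop("edge weights must be non-negative")
  if (max(abs(W - t(W))) > 1e-12) stop("weight matrix must be symmetric")
  if (any(diag(W) != 0)) stop("weight matrix must have zero diagonal")
  dimnames(W) <- list(nodes, nodes)
  d <- rowSums(W)
  L <- diag(d, p) - W
  dimnames(L) <- dimnames(W)
  structure(list(nodes = nodes, W = W, degree = d, laplacian = L),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat("region_graph:", length(x$nodes), "nodes,", ne, "edges",
      if (graph_is_connected(x)) "(connected)\n" else "(disconnected)\n")
  invisible(x)
}

#' Graph Laplacian
#'
#' @param graph A `region_graph`.
#' @return The combinatorial Laplacian `L = D - W` (dense matrix).
#' @export
laplacian <- function(graph) {
  stopifnot(inherits(graph, "region_graph"))
  graph$laplacian
}

#' Is the graph connected?
#'
#' Breadth-first search over positive-weight edges.
#'
#' @param graph A `region_graph`.
#' @return Logical.
#' @export
graph_is_connected <- function(graph) {
  p <- length(graph$nodes)
  if (p == 0) return(TRUE)
  seen <- logical(p)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(graph$W[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Within-hemisphere anatomical adjacency used by the template graph.
cortical_adjacency <- function() {
  rbind(
    c("frontal", "parietal"),  c("frontal", "temporal"),
    c("frontal", "cingulate"), c("frontal", "insula"),
    c("temporal", "parietal"), c("temporal", "insula"),
    c("temporal", "occipital"), c("parietal", "occipital"),
    c("parietal", "cingulate"), c("cingulate", "insula"))
}

subcortical_adjacency <- function() {
  rbind(
    c("hippocampus", "amygdala"), c("caudate", "putamen"),
    c("putamen", "pallidum"),     c("putamen", "accumbens"),
    c("caudate", "accumbens"),    c("thalamus", "pallidum"),
    c("hippocampus", "thalamus"))
}

# Each subcortical structure is tied to one cortical lobe of its own
# hemisphere (medial-temporal structures to temporal cortex, basal
# ganglia and thalamus to frontal cortex).
subcortical_cortex_links <- function() {
  rbind(
    c("hippocampus", "temporal"), c("amygdala", "temporal"),
    c("caudate", "frontal"),      c("putamen", "frontal"),
    c("accumbens", "frontal"),    c("pallidum", "frontal"),
    c("thalamus", "frontal"))
}

#' Build the anatomical template ("skeleton") graph
#'
#' Unit-weight edges connect (a) every left-right homologue pair,
#' (b) anatomically adjacent cortical lobes within each hemisphere,
#' (c) related subcortical structures within each hemisphere,
#' (d) each subcortical structure to its hemisphere's frontal or
#' temporal cortex, and (e) the cerebellum to both thalami.  On the
#' default 27-measure scheme the result is connected.
#'
#' @param scheme A `parcellation_scheme`.
#' @return A `region_graph`.
#' @export
build_template_graph <- function(scheme) {
  scheme <- validate_parcellation(scheme)
  hp <- homologue_pairs(scheme)
  if (nrow(hp) == 0)
    stop("scheme has no left-right homologue pairs; template graph undefined")
  p <- nrow(scheme)
  W <- matrix(0, p, p, dimnames = list(scheme$measure, scheme$measure))
  add_edge <- function(a, b) {
    if (length(a) == 1 && length(b) == 1 &&
        a %in% scheme$measure && b %in% scheme$measure && a != b) {
      W[a, b] <<- 1; W[b, a] <<- 1
    }
  }
  for (i in seq_len(nrow(hp))) add_edge(hp$left[i], hp$right[i])
  by_struct <- function(structure, hemi) {
    scheme$measure[scheme$structure == structure & scheme$hemisphere == hemi]
  }
  for (hemi in c("left", "right")) {
    for (tab in list(cortical_adjacency(), subcortical_adjacency(),
                     subcortical_cortex_links())) {
      for (i in seq_len(nrow(tab)))
        add_edge(by_struct(tab[i, 1], hemi), by_struct(tab[i, 2], hemi))
    }
  }
  cb <- scheme$measure[scheme$structure == "cerebellum"]
  if (length(cb) == 1) {
    for (hemi in c("left", "right"))
      add_edge(cb, by_struct("thalamus", hemi))
  }
  region_graph(scheme$measure, W)
}

#' Build a data-driven correlation graph
#'
#' Puts a unit edge between two measures whenever the absolute Pearson
#' correlation of their percent-of-TIV columns reaches `tau`.  A
#' constant column correlates with nothing.
#'
#' @param X A `normalized_volume_table` (or plain data frame of
#'   measure columns plus `subject_id`).
#' @param tau Absolute-correlation threshold in (0, 1].
#' @return A `region_graph`.
#' @export
build_correlation_graph <- function(X, tau) {
  stopifnot(is.data.frame(X), is.numeric(tau), length(tau) == 1,
            tau > 0, tau <= 1)
  M <- as.matrix(X[, setdiff(names(X), "subject_id"), drop = FALSE])
  if (nrow(M) < 3) stop("need at least 3 subjects to estimate correlations")
  sds <- apply(M, 2, stats::sd)
  R <- suppressWarnings(stats::cor(M))
  R[!is.finite(R)] <- 0          # constant columns: treat r as 0
  R[, sds == 0] <- 0
  R[sds == 0, ] <- 0
  W <- (abs(R) >= tau - 1e-12) * 1   # tolerate fp error at |r| = tau
  diag(W) <- 0
  region_graph(colnames(M), W)
}

#' Read / write a region graph as an edge list
#'
#' Plain text, comma-separated, columns `from`, `to`, `weight`.  Nodes
#' listed in `nodes` but absent from the edge list become isolated.
#'
#' @param graph A `region_graph`.
#' @param path File path.
#' @export
write_edge_list <- function(graph, path) {
  idx <- which(upper.tri(graph$W) & graph$W > 0, arr.ind = TRUE)
  el <- data.frame(from = graph$nodes[idx[, 1]],
                   to = graph$nodes[idx[, 2]],
                   weight = graph$W[idx])
  el <- el[order(el$from, el$to), , drop = FALSE]
  utils::write.csv(el, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_edge_list
#' @param nodes Character vector of node names (fixes the node order).
#' @export
read_edge_list <- function(path, nodes) {
  el <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("from", "to", "weight") %in% names(el)))
  unknown <- setdiff(c(el$from, el$to), nodes)
  if (length(unknown))
    stop("edge list refers to unknown node(s): ",
         paste(unique(unknown), collapse = ", "))
  p <- length(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(el))) {
    W[el$from[i], el$to[i]] <- el$weight[i]
    W[el$to[i], el$from[i]] <- el$weight[i]
  }
  region_graph(nodes, W)
}
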