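#' @importFrom Matrix Diagonal drop0 colSums sparseMatrix t
NULL

# Canonical MCL on one connected component's sparse adjacency matrix.
# Returns an integer cluster assignment per column of A.
.mclCore <- function(A, inflation, maxIter, tol, pruneThreshold) {
  n <- nrow(A)
  if (n == 1L) return(1L)
  # self-loop weight: maximum incident edge weight per node
  selfw <- apply(A, 2L, max)
  selfw[selfw <= 0] <- 1
  M <- A + Diagonal(n, selfw)
  normalize <- function(M) {
    cs <- colSums(M)
    cs[cs == 0] <- 1
    M %*% Diagonal(n, 1 / cs)
  }
  M <- normalize(M)
  for (it in seq_len(maxIter)) {
    Mold <- M
    M <- M %*% M                       # expansion
    M <- drop0(M)
    M@x <- M@x^inflation               # inflation
    M <- normalize(M)
    M <- drop0(M, tol = pruneThreshold)
    M <- normalize(M)
    resid <- max(abs(M - Mold))
    if (resid < tol) {
      # clusters: connected components of the limit matrix's support
      S <- drop0(M + Matrix::t(M))
      g <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
      return(igraph::components(g)$membership)
    }
  }
  stop(sprintf(
    "MCL did not converge in %d iterations (residual %.3g > %.3g)",
    maxIter, resid, tol))
}

#' Markov clustering of the same-function protein graph
#'
#' Canonical MCL: the edge weights are turned into a column-stochastic
#' transition matrix (with a self-loop per node equal to its maximum
#' incident edge weight), then expansion (matrix squaring) and inflation
#' (entrywise power followed by column renormalisation) alternate until
#' the matrix stops changing; clusters are read from the attractor
#' structure of the limit matrix. Connected components are clustered
#' independently (expansion never crosses a component boundary), and
#' isolated nodes become singleton groups. Nodes are processed in
#' lexicographic protein-id order, so the result is deterministic across
#' runs and platforms; group ids are assigned by each group's
#' lexicographically smallest member.
#'
#' @param graph same-function graph from [buildFunctionGraph()].
#' @param inflation inflation exponent, > 1; default 1.4, a conservative
#'   setting that yields relatively coarse clusters.
#' @param maxIter iteration cap; non-convergence raises an error
#'   reporting the residual.
#' @param tol convergence tolerance on the max absolute change between
#'   successive matrices.
#' @param pruneThreshold entries below this are dropped after each
#'   inflation step (standard MCL pruning).
#' @return a [FunctionGroups-class] partition of all graph nodes.
#' @export
mclCluster <- function(graph, inflation = 1.4, maxIter = 100L,
                       tol = 1e-8, pruneThreshold = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) stop("graph nodes must be named by protein id")
  ord <- order(nodes)
  comp <- igraph::components(graph)
  membership <- rep(NA_character_, length(nodes))
  names(membership) <- nodes
  cluster_members <- list()
  for (ci in seq_len(comp$no)) {
    ids <- nodes[comp$membership == ci]
    ids <- sort(ids)
    if (length(ids) == 1L) {
      cluster_members[[length(cluster_members) + 1L]] <- ids
      next
    }
    sub <- igraph::induced_subgraph(graph, ids)
    # canonical node order inside the component
    perm <- match(sort(igraph::V(sub)$name), igraph::V(sub)$name)
    sub <- igraph::permute(sub, order(perm))
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = TRUE)
    cl <- .mclCore(A, inflation, maxIter, tol, pruneThreshold)
    for (k in sort(unique(cl))) {
      cluster_members[[length(cluster_members) + 1L]] <-
        rownames(A)[cl == k]
    }
  }
  # deterministic ids: order groups by their smallest member
  firsts <- vapply(cluster_members, function(x) min(x), character(1))
  cluster_members <- cluster_members[order(firsts)]
  width <- max(6L, nchar(length(cluster_members)))
  for (i in seq_along(cluster_members)) {
    gid <- sprintf("FG%0*d", width, i)
    membership[cluster_members[[i]]] <- gid
  }
  new("FunctionGroups", membership = membership,
      category = character(0), scope = character(0))
}
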