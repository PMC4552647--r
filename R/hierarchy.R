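# Layered single-linkage hierarchy and tree-topology correlation.

.njNewick <- function(subtrees, d) {
  # subtrees: character vector of newick fragments (no trailing ';')
  # d: symmetric distance matrix over them
  k <- length(subtrees)
  if (k == 2L)
    return(sprintf("(%s:%.8g,%s:%.8g)", subtrees[1L], d[1L, 2L] / 2,
                   subtrees[2L], d[1L, 2L] / 2))
  ph <- sprintf("ZQZ%dQZQ", seq_len(k))
  dimnames(d) <- list(ph, ph)
  tr <- ape::nj(stats::as.dist(d))
  nwk <- ape::write.tree(tr)
  nwk <- sub(";$", "", nwk)
  for (i in seq_len(k))
    nwk <- gsub(ph[i], subtrees[i], nwk, fixed = TRUE)
  nwk
}

#' Build a layered single-linkage hierarchy of a similarity network
#'
#' Starting from a single cluster of all organisms at similarity 0 and
#' moving upward in fixed increments, each cluster at cut-off X is
#' refined into its single-linkage clusters at the next cut-off; the
#' distance between two sibling clusters is 1 minus the mean of all
#' inter-cluster pairwise similarities, and siblings are related by a
#' neighbor-joining tree. Layers are stitched into one tree by
#' substituting every cluster node with its refinement subtree.
#' Organisms still co-clustered at the top cut-off (identical
#' repertoires) end as a zero-branch-length polytomy.
#'
#' The combined structure is a compact representation of functional
#' similarity; it is not a phylogeny and does not convey evolutionary
#' relationships.
#'
#' @param network a [SimilarityNetwork-class].
#' @param increment layer step as a similarity fraction; default 0.01
#'   (100 layers).
#' @return a [LayeredHierarchy-class].
#' @export
buildLayeredHierarchy <- function(network, increment = 0.01) {
  stopifnot(is(network, "SimilarityNetwork"),
            increment > 0, increment <= 1)
  s <- similarityMatrix(network)
  orgs <- rownames(s)
  cutoffs <- seq(increment, 1, by = increment)
  memberships <- lapply(cutoffs, function(co)
    singleLinkageClusters(network, co))
  names(memberships) <- sprintf("%.6g", cutoffs)

  clustersAt <- function(set, k) {
    # restriction of the global layer-k partition to `set`
    # (valid because single-linkage clusters nest across cut-offs)
    part <- memberships[[k]][set]
    unname(split(set, part))
  }
  recurse <- function(set, k) {
    if (length(set) == 1L) return(set)
    if (k > length(cutoffs))
      return(paste0("(", paste0(set, ":0", collapse = ","), ")"))
    cl <- clustersAt(set, k)
    if (length(cl) == 1L) return(recurse(set, k + 1L))
    subs <- vapply(cl, function(x) recurse(x, k + 1L), character(1))
    d <- matrix(0, length(cl), length(cl))
    for (i in seq_along(cl)) for (j in seq_along(cl)) if (i < j) {
      d[i, j] <- d[j, i] <- 1 - mean(s[cl[[i]], cl[[j]], drop = FALSE])
    }
    .njNewick(subs, d)
  }
  nwk <- recurse(orgs, 1L)
  if (!grepl("^\\(", nwk)) nwk <- paste0("(", nwk, ")")
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  new("LayeredHierarchy", tree = tree, cutoffs = cutoffs,
      memberships = memberships)
}

.leafStepMatrix <- function(tree) {
  ntip <- length(tree$tip.label)
  g <- igraph::make_graph(t(tree$edge), directed = FALSE)
  d <- igraph::distances(g, v = seq_len(ntip), to = seq_len(ntip))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Topological correlation between two hierarchies
#'
#' Each hierarchy is reduced to an all-pairs leaf distance matrix in
#' which the distance between two organisms is the number of steps
#' (edges) on the path between them; the correlation between the two
#' vectorised matrices measures how similarly the hierarchies arrange
#' the organisms. The number of layers does not matter for this
#' comparison, only the relative topological distances.
#'
#' @param h1,h2 [ape::phylo] trees or [LayeredHierarchy-class] objects
#'   over the same leaf set.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return correlation in [-1, 1].
#' @export
hierarchyCorrelation <- function(h1, h2,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is(h1, "LayeredHierarchy")) h1 <- hierarchyTree(h1)
  if (is(h2, "LayeredHierarchy")) h2 <- hierarchyTree(h2)
  l1 <- sort(h1$tip.label)
  l2 <- sort(h2$tip.label)
  if (!identical(l1, l2)) {
    diff <- c(setdiff(l1, l2), setdiff(l2, l1))
    stop("hierarchies have different leaf sets; offending leaves: ",
         paste(diff, collapse = ", "))
  }
  d1 <- .leafStepMatrix(h1)[l1, l1]
  d2 <- .leafStepMatrix(h2)[l1, l1]
  stats::cor(d1[lower.tri(d1)], d2[lower.tri(d2)], method = method)
}
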