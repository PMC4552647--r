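#' Detect organism modules by resolution-tuned Louvain
#'
#' Runs weighted Louvain community detection on the complete similarity
#' network (no cut-off is applied: edge weight alone drives the
#' grouping). The `resolution` parameter controls coarseness the way a
#' Markov-stability time horizon would: larger values yield larger,
#' coarser (more functionally diverse) modules. Internally the
#' modularity null-model term is scaled by 1/resolution to obtain this
#' behaviour. Louvain is not deterministic in general; the run is made
#' reproducible by seeding the node-visit order, and an optional
#' consensus mode reruns the algorithm `consensus` times and keeps the
#' majority co-assignments.
#'
#' @param network a [SimilarityNetwork-class].
#' @param resolution positive coarseness parameter; default 1.
#' @param seed integer seed; same seed, same partition.
#' @param consensus optional integer k: run k seeded replicates and
#'   return the components of the majority (> k/2) co-assignment graph.
#' @return a [ModulePartition-class].
#' @export
louvainPartition <- function(network, resolution = 1, seed = 1L,
                             consensus = NULL) {
  stopifnot(is(network, "SimilarityNetwork"), resolution > 0)
  s <- similarityMatrix(network)
  orgs <- rownames(s)
  g <- igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  runOnce <- function(sd) {
    .withSeed(sd, {
      cl <- igraph::cluster_louvain(g, resolution = 1 / resolution)
      stats::setNames(igraph::membership(cl), orgs)
    })
  }
  if (is.null(consensus)) {
    memb <- runOnce(as.integer(seed))
  } else {
    k <- as.integer(consensus)
    stopifnot(k >= 1L)
    n <- length(orgs)
    co <- matrix(0L, n, n)
    for (r in seq_len(k)) {
      m <- runOnce(as.integer(seed) + r - 1L)
      co <- co + outer(m, m, "==")
    }
    adj <- co > k / 2
    diag(adj) <- FALSE
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- stats::setNames(igraph::components(gg)$membership, orgs)
  }
  assignment <- .rankedIds(stats::setNames(as.character(memb), orgs), "M")
  new("ModulePartition", assignment = assignment,
      resolution = as.numeric(resolution), seed = as.integer(seed))
}

# Pair-assignment counts between two partitions over the same elements.
.pairCounts <- function(p1, p2) {
  tab <- table(p1, p2)
  both <- sum(choose(as.numeric(tab), 2))
  same1 <- sum(choose(as.numeric(rowSums(tab)), 2))
  same2 <- sum(choose(as.numeric(colSums(tab)), 2))
  list(both = both, only1 = same1 - both, only2 = same2 - both)
}

#' Pair-assignment Jaccard between two partitions
#'
#' The number of unordered organism pairs co-assigned in both
#' partitions divided by the number co-assigned in at least one.
#' Symmetric and invariant to relabelling; 1 for identical partitions,
#' 0 when no co-assigned pair is shared.
#'
#' @param p1,p2 [ModulePartition-class] objects or named character
#'   vectors over the same organism set.
#' @return Jaccard fraction in [0, 1] (0 when neither partition
#'   co-assigns any pair).
#' @export
partitionCorrespondence <- function(p1, p2) {
  if (is(p1, "ModulePartition")) p1 <- moduleAssignment(p1)
  if (is(p2, "ModulePartition")) p2 <- moduleAssignment(p2)
  if (!setequal(names(p1), names(p2)))
    stop("partitions cover different organism sets; difference: ",
         paste(c(setdiff(names(p1), names(p2)),
                 setdiff(names(p2), names(p1))), collapse = ", "))
  p2 <- p2[names(p1)]
  cc <- .pairCounts(p1, p2)
  denom <- cc$both + cc$only1 + cc$only2
  if (denom == 0) return(0)
  cc$both / denom
}

#' Jaccard comparison of modules against a taxonomy level
#'
#' Counts unordered organism pairs assigned to both the same module and
#' the same taxon, to the same module only, and to the same taxon only;
#' the Jaccard index is both / (both + module-only + taxon-only). Pairs,
#' not organisms, are the comparison unit.
#'
#' @param partition a [ModulePartition-class] or named character vector.
#' @param taxonomy data.frame as from [readTaxonomy()].
#' @param level one of [TAXONOMY_RANKS].
#' @return list with `jaccard`, `both`, `moduleOnly`, `taxonOnly`.
#' @export
moduleTaxonomyJaccard <- function(partition, taxonomy, level) {
  if (is(partition, "ModulePartition"))
    partition <- moduleAssignment(partition)
  taxa <- .levelTaxa(taxonomy, level, names(partition))
  if (anyNA(taxa))
    stop("organism(s) without a taxon at level ", level, ": ",
         paste(names(partition)[is.na(taxa)], collapse = ", "))
  cc <- .pairCounts(partition, taxa)
  denom <- cc$both + cc$only1 + cc$only2
  list(jaccard = if (denom == 0) 0 else cc$both / denom,
       both = cc$both, moduleOnly = cc$only1, taxonOnly = cc$only2)
}
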