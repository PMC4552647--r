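# Shared fixtures and independent oracles for the test suite.

# Taxonomy data.frame from a named list organism -> lineage vector
# (species..phylum, padded with the organism id where unspecified).
makeTaxonomy <- function(lineages) {
  rows <- lapply(names(lineages), function(org) {
    lin <- lineages[[org]]
    full <- stats::setNames(rep(NA_character_, 6), fusionet::TAXONOMY_RANKS)
    full[names(lin)] <- lin
    data.frame(organism_id = org, t(full), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Single-level taxonomy: every rank equals the given taxon label.
flatTaxonomy <- function(taxa) {
  data.frame(organism_id = names(taxa),
             species = unname(taxa), genus = unname(taxa),
             family = unname(taxa), order = unname(taxa),
             class = unname(taxa), phylum = unname(taxa),
             stringsAsFactors = FALSE)
}

# Similarity network from a symmetric matrix given as pair list.
pairNetwork <- function(orgs, pairs) {
  s <- matrix(0, length(orgs), length(orgs), dimnames = list(orgs, orgs))
  for (p in pairs) s[p[[1]], p[[2]]] <- s[p[[2]], p[[1]]] <- p[[3]]
  diag(s) <- 1
  fusionet::SimilarityNetwork(s)
}

# Independent dense-matrix MCL oracle (base R, no sparse algebra);
# cluster readout via igraph components of the limit support.
denseMclOracle <- function(adj, inflation, maxIter = 200) {
  n <- nrow(adj)
  diag(adj) <- apply(adj, 2, max)
  diag(adj)[diag(adj) <= 0] <- 1
  norm <- function(m) sweep(m, 2, pmax(colSums(m), .Machine$double.eps), "/")
  M <- norm(adj)
  for (i in seq_len(maxIter)) {
    Mold <- M
    M <- M %*% M
    M <- norm(M^inflation)
    M[M < 1e-6] <- 0
    M <- norm(M)
    if (max(abs(M - Mold)) < 1e-8) break
  }
  sup <- (M + t(M)) > 0
  diag(sup) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(sup, mode = "undirected")
  stats::setNames(igraph::components(g)$membership, rownames(adj))
}

# Exhaustive O(n^2) pair-assignment Jaccard oracle.
pairJaccardOracle <- function(p1, p2) {
  p2 <- p2[names(p1)]
  ids <- names(p1)
  both <- either <- 0L
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    s1 <- p1[[i]] == p1[[j]]
    s2 <- p2[[i]] == p2[[j]]
    if (s1 && s2) both <- both + 1L
    if (s1 || s2) either <- either + 1L
  }
  if (either == 0L) return(0)
  both / either
}

# Leaf-to-leaf step counts via unit branch lengths and ape's
# node-distance machinery (independent of the igraph-based path).
leafStepsOracle <- function(tree) {
  t2 <- tree
  t2$edge.length <- rep(1, nrow(t2$edge))
  d <- ape::dist.nodes(t2)[seq_along(t2$tip.label), seq_along(t2$tip.label)]
  dimnames(d) <- list(t2$tip.label, t2$tip.label)
  d
}

# High-precision evaluation of the HSSP curve via the log form --
# an algebraically different expression of the same quantity.
hsspOracle <- function(L, Id) {
  ifelse(L < 11, -99,
    ifelse(L <= 450,
      Id - exp(log(480) - 0.32 * (1 + exp(-L / 1000)) * log(L)),
      Id - 19.5))
}
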