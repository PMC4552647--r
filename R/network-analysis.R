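#' Single-linkage clusters of a similarity network at a cut-off
#'
#' Keeps only edges with similarity >= `cutoff` (the same `>=`
#' convention used for the HSSP threshold) and returns the connected
#' components: any two organisms sharing a retained edge land in one
#' cluster regardless of their similarity to other members. Organisms
#' with no retained edge become singleton clusters.
#'
#' @param network a [SimilarityNetwork-class].
#' @param cutoff similarity fraction in [0, 1].
#' @return named character vector organism id -> cluster id; cluster
#'   ids are assigned by each cluster's lexicographically smallest
#'   member.
#' @export
singleLinkageClusters <- function(network, cutoff) {
  stopifnot(is(network, "SimilarityNetwork"),
            length(cutoff) == 1L, cutoff >= 0, cutoff <= 1)
  s <- similarityMatrix(network)
  adj <- s >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  orgs <- rownames(s)
  firsts <- vapply(split(orgs, comp), min, character(1))
  ranks <- rank(firsts, ties.method = "first")
  width <- max(4L, nchar(length(firsts)))
  stats::setNames(sprintf("SL%0*d", width, ranks[comp]), orgs)
}

.levelTaxa <- function(taxonomy, level, orgs) {
  if (!level %in% TAXONOMY_RANKS)
    stop("unknown taxonomy level: ", level)
  checkTaxonomyCovers(taxonomy, orgs)
  stats::setNames(taxonomy[[level]], taxonomy$organism_id)[orgs]
}

#' Overall accuracy of a clustering against a taxonomy level
#'
#' Every organism in a cluster is assigned the cluster's most common
#' (modal) taxon -- in a cluster of three organisms of which two are of
#' taxon X, all three are assigned to X. Overall accuracy is the total
#' number of correctly assigned organisms divided by the total number
#' of organisms. Organisms with no taxon at the level are excluded and
#' reported via the `excluded` attribute.
#'
#' @param partition named character vector organism id -> cluster id.
#' @param taxonomy data.frame as from [readTaxonomy()].
#' @param level one of [TAXONOMY_RANKS].
#' @param tieBreak how to score a cluster whose modal taxon is tied:
#'   `"lexicographic"` (default) counts only the lexicographically
#'   smallest tied taxon as the winner; `"either"` counts members of
#'   any tied taxon as correct.
#' @return accuracy fraction in [0, 1], with attribute `excluded`
#'   listing organisms without a taxon at the level.
#' @export
overallAccuracy <- function(partition, taxonomy, level,
                            tieBreak = c("lexicographic", "either")) {
  tieBreak <- match.arg(tieBreak)
  if (!length(partition)) stop("empty partition")
  taxa <- .levelTaxa(taxonomy, level, names(partition))
  excluded <- names(partition)[is.na(taxa)]
  keep <- !is.na(taxa)
  if (!any(keep)) stop("no organism has a taxon at level ", level)
  part <- partition[keep]
  taxa <- taxa[keep]
  correct <- 0L
  for (cl in unique(part)) {
    tab <- table(taxa[part == cl])
    if (tieBreak == "lexicographic") {
      # table() orders names lexicographically, so the first maximum
      # is the lexicographically smallest tied taxon
      correct <- correct + max(tab)
    } else {
      correct <- correct + sum(tab[tab == max(tab)])
    }
  }
  out <- as.numeric(correct) / length(part)
  attr(out, "excluded") <- excluded
  out
}

#' Per-taxon and overall coverage of a clustering
#'
#' For each taxon at the level, the major cluster is the cluster
#' containing the most of its members (ties broken by the smallest
#' lexicographic cluster id), and coverage is the fraction of the
#' taxon's members in that cluster; 7 members with 4 in the major
#' cluster gives coverage 4/7. Overall coverage is the fraction of taxa
#' with 100 percent coverage among taxa with at least two members
#' (single-member taxa would contribute trivially and are excluded).
#'
#' @inheritParams overallAccuracy
#' @return list with `perTaxon` (named coverage fractions),
#'   `majorCluster` (named cluster ids), `overall` (fraction), and
#'   `excluded` (organisms without a taxon at the level).
#' @export
taxonCoverage <- function(partition, taxonomy, level) {
  if (!length(partition)) stop("empty partition")
  taxa <- .levelTaxa(taxonomy, level, names(partition))
  excluded <- names(partition)[is.na(taxa)]
  keep <- !is.na(taxa)
  if (!any(keep)) stop("no organism has a taxon at level ", level)
  part <- partition[keep]
  taxa <- taxa[keep]
  per <- vapply(split(part, taxa), function(cl) {
    tab <- table(cl)   # lexicographic cluster-id order; first max wins
    max(tab) / length(cl)
  }, numeric(1))
  major <- vapply(split(part, taxa), function(cl) {
    tab <- table(cl)
    names(tab)[which.max(tab)]
  }, character(1))
  sizes <- table(taxa)
  multi <- names(sizes)[sizes >= 2L]
  overall <- if (length(multi)) {
    sum(per[multi] >= 1 - 1e-12) / length(multi)
  } else NA_real_
  list(perTaxon = per, majorCluster = major, overall = overall,
       excluded = excluded)
}

#' Sweep single-linkage cut-offs against taxonomy levels
#'
#' Evaluates [overallAccuracy()] and [taxonCoverage()] for every
#' (cut-off, level) combination. Accuracy tends to rise and coverage to
#' fall with the cut-off; the lowest cut-off reaching accuracy 1 and
#' the highest retaining coverage 1 bound the similarity range over
#' which the taxonomy level can be assigned (see
#' [concordanceBounds()]).
#'
#' @param network a [SimilarityNetwork-class].
#' @param taxonomy data.frame as from [readTaxonomy()].
#' @param cutoffs numeric vector of similarity cut-offs; default 5
#'   percent to 100 percent in steps of 5 percent.
#' @param levels taxonomy levels to evaluate; default all six.
#' @return data.frame with columns `cutoff`, `level`, `n_clusters`,
#'   `overall_accuracy`, `overall_coverage`.
#' @export
sweepCutoffs <- function(network, taxonomy,
                         cutoffs = seq(0.05, 1, by = 0.05),
                         levels = TAXONOMY_RANKS) {
  stopifnot(is(network, "SimilarityNetwork"))
  rows <- vector("list", length(cutoffs) * length(levels))
  k <- 0L
  for (co in cutoffs) {
    part <- singleLinkageClusters(network, co)
    for (lev in levels) {
      acc <- overallAccuracy(part, taxonomy, lev)
      cov <- taxonCoverage(part, taxonomy, lev)
      k <- k + 1L
      rows[[k]] <- data.frame(cutoff = co, level = lev,
                              n_clusters = length(unique(part)),
                              overall_accuracy = as.numeric(acc),
                              overall_coverage = cov$overall)
    }
  }
  do.call(rbind, rows)
}

#' Lower and upper concordance bounds per taxonomy level
#'
#' The lower bound is the minimum cut-off with overall accuracy 1 (at
#' or above it, organisms in different clusters are of different taxa);
#' the upper bound is the maximum cut-off with overall coverage 1 (at
#' or below it, no taxon is split). The interval between them is the
#' range of uncertainty of taxonomic assignment.
#'
#' @param sweep data.frame from [sweepCutoffs()].
#' @return data.frame with columns `level`, `lower_bound`,
#'   `upper_bound` (NA when never attained).
#' @export
concordanceBounds <- function(sweep) {
  levs <- unique(sweep$level)
  out <- lapply(levs, function(lev) {
    sl <- sweep[sweep$level == lev, ]
    lo <- sl$cutoff[sl$overall_accuracy >= 1 - 1e-12]
    hi <- sl$cutoff[!is.na(sl$overall_coverage) &
                      sl$overall_coverage >= 1 - 1e-12]
    data.frame(level = lev,
               lower_bound = if (length(lo)) min(lo) else NA_real_,
               upper_bound = if (length(hi)) max(hi) else NA_real_)
  })
  do.call(rbind, out)
}
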