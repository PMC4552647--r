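#' Organism ids of an object
#' @param x an object carrying organisms.
#' @return character vector of organism ids.
#' @export
setGeneric("organisms", function(x) standardGeneric("organisms"))

#' Group ids of a FunctionGroups partition
#' @param x a [FunctionGroups-class] object.
#' @return character vector of group ids (lexicographic order).
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' Number of groups / modules
#' @param x a partition-like object.
#' @return integer count.
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @describeIn FunctionGroups-class group ids
#' @param x object
setMethod("groupIds", "FunctionGroups",
          function(x) sort(unique(unname(x@membership))))

#' @describeIn FunctionGroups-class number of groups
setMethod("nGroups", "FunctionGroups",
          function(x) length(unique(x@membership)))

#' Protein membership of a FunctionGroups partition
#'
#' @param x a [FunctionGroups-class] object.
#' @return named character vector protein id -> group id.
#' @export
proteinGroups <- function(x) {
  stopifnot(is(x, "FunctionGroups"))
  x@membership
}

#' Members of one or all function groups
#'
#' @param x a [FunctionGroups-class] object.
#' @param group optional group id; when missing, a named list of all
#'   groups is returned.
#' @return character vector of protein ids, or a list of them.
#' @export
groupMembers <- function(x, group) {
  stopifnot(is(x, "FunctionGroups"))
  if (missing(group)) return(split(names(x@membership), x@membership))
  if (!group %in% x@membership) stop("unknown group id: ", group)
  names(x@membership)[x@membership == group]
}

#' Group sizes
#' @param x a [FunctionGroups-class] object.
#' @return named integer vector of member counts per group.
#' @export
groupSizes <- function(x) {
  stopifnot(is(x, "FunctionGroups"))
  tab <- table(x@membership)
  structure(as.integer(tab), names = names(tab))
}

#' Per-group annotation category (Kn/Hy/Un)
#' @param x a [FunctionGroups-class] object.
#' @return named character vector group id -> category (NA when unset).
#' @export
groupCategory <- function(x) {
  stopifnot(is(x, "FunctionGroups"))
  gids <- groupIds(x)
  out <- structure(rep(NA_character_, length(gids)), names = gids)
  if (length(x@category)) out[names(x@category)] <- x@category
  out
}

#' Per-group scope (shared/unique)
#' @param x a [FunctionGroups-class] object.
#' @return named character vector group id -> scope (NA when unset).
#' @export
groupScope <- function(x) {
  stopifnot(is(x, "FunctionGroups"))
  gids <- groupIds(x)
  out <- structure(rep(NA_character_, length(gids)), names = gids)
  if (length(x@scope)) out[names(x@scope)] <- x@scope
  out
}

#' @describeIn SimilarityNetwork-class organism ids
setMethod("organisms", "SimilarityNetwork", function(x) rownames(x@sim))

#' @describeIn ModulePartition-class organism ids
setMethod("organisms", "ModulePartition", function(x) names(x@assignment))

#' @describeIn BipartiteNetwork-class organism ids
setMethod("organisms", "BipartiteNetwork", function(x) x@organisms)

#' @describeIn ModulePartition-class number of modules
setMethod("nGroups", "ModulePartition",
          function(x) length(unique(x@assignment)))

#' Similarity matrix of a network
#' @param x a [SimilarityNetwork-class].
#' @return dense symmetric numeric matrix, unit diagonal, entries in [0,1].
#' @export
similarityMatrix <- function(x) {
  stopifnot(is(x, "SimilarityNetwork"))
  x@sim
}

#' Number of (complete-graph) edges of a similarity network
#'
#' Every unordered organism pair carries one weighted edge, so a network
#' over n organisms has n(n-1)/2 edges.
#' @param x a [SimilarityNetwork-class].
#' @return integer edge count.
#' @export
edgeCount <- function(x) {
  stopifnot(is(x, "SimilarityNetwork"))
  n <- nrow(x@sim)
  as.integer(n * (n - 1) / 2)
}

#' Module assignment of a partition
#' @param x a [ModulePartition-class].
#' @return named character vector organism id -> module id.
#' @export
moduleAssignment <- function(x) {
  stopifnot(is(x, "ModulePartition"))
  x@assignment
}

#' Layer cut-offs of a layered hierarchy
#' @param x a [LayeredHierarchy-class].
#' @return numeric vector of cut-offs.
#' @export
layerCutoffs <- function(x) {
  stopifnot(is(x, "LayeredHierarchy"))
  x@cutoffs
}

#' Combined tree of a layered hierarchy
#' @param x a [LayeredHierarchy-class].
#' @return an [ape::phylo] tree with organisms as tips.
#' @export
hierarchyTree <- function(x) {
  stopifnot(is(x, "LayeredHierarchy"))
  x@tree
}

setMethod("show", "FunctionGroups", function(object) {
  sz <- groupSizes(object)
  cat(sprintf("FunctionGroups: %d proteins in %d groups (%d singletons)\n",
              length(object@membership), length(sz), sum(sz == 1L)))
  cc <- groupCategory(object)
  if (!all(is.na(cc))) {
    tab <- table(factor(cc, levels = c("Kn", "Hy", "Un")))
    cat(sprintf("  categories: Kn=%d Hy=%d Un=%d\n",
                tab[["Kn"]], tab[["Hy"]], tab[["Un"]]))
  }
  sc <- groupScope(object)
  if (!all(is.na(sc)))
    cat(sprintf("  scope: shared=%d unique=%d\n",
                sum(sc == "shared", na.rm = TRUE),
                sum(sc == "unique", na.rm = TRUE)))
  invisible(NULL)
})

setMethod("show", "SimilarityNetwork", function(object) {
  n <- nrow(object@sim)
  off <- object@sim[lower.tri(object@sim)]
  cat(sprintf("SimilarityNetwork: %d organisms, %d edges\n",
              n, as.integer(n * (n - 1) / 2)))
  if (length(off))
    cat(sprintf("  similarity mean %.3f, median %.3f, range [%.3f, %.3f]\n",
                mean(off), stats::median(off), min(off), max(off)))
  invisible(NULL)
})

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf(
    "ModulePartition: %d organisms in %d modules (resolution %.3g, seed %d)\n",
    length(object@assignment), length(unique(object@assignment)),
    object@resolution, object@seed))
  invisible(NULL)
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat(sprintf(
    "BipartiteNetwork: %d organisms, %d function groups, %d edges\n",
    length(object@organisms), length(object@functionGroups),
    nrow(object@edges)))
  invisible(NULL)
})

setMethod("show", "LayeredHierarchy", function(object) {
  cat(sprintf("LayeredHierarchy: %d layers over %d organisms\n",
              length(object@cutoffs), length(object@tree$tip.label)))
  invisible(NULL)
})
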