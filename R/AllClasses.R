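#' @import methods
NULL

#' FunctionGroups: a partition of proteins into molecular-function groups
#'
#' Proteins connected (directly or transitively) by same-function
#' alignments are clustered into function groups; each group proxies one
#' molecular function without naming it. The object stores the partition
#' as a named membership vector (protein id -> group id) together with
#' optional per-group annotation category (\code{Kn}/\code{Hy}/\code{Un})
#' and scope (\code{shared}/\code{unique}).
#'
#' @slot membership named character vector mapping protein id to group id.
#' @slot category named character vector mapping group id to one of
#'   \code{"Kn"}, \code{"Hy"}, \code{"Un"} (or \code{NA} before annotation).
#' @slot scope named character vector mapping group id to \code{"shared"}
#'   or \code{"unique"} (or \code{NA} before organism mapping).
#'
#' @seealso [mclCluster()], [categorizeGroups()], [tagScope()]
#' @export
setClass("FunctionGroups",
  slots = c(membership = "character",
            category   = "character",
            scope      = "character"))

setValidity("FunctionGroups", function(object) {
  m <- object@membership
  if (length(m) == 0L) return("membership must be non-empty")
  if (is.null(names(m)) || anyNA(names(m)) || any(names(m) == ""))
    return("membership must be named by protein id")
  if (anyDuplicated(names(m)))
    return("each protein must belong to exactly one group")
  if (anyNA(m) || any(m == ""))
    return("group ids must be non-empty")
  gids <- unique(m)
  for (slotname in c("category", "scope")) {
    v <- slot(object, slotname)
    if (length(v) && (is.null(names(v)) || !all(names(v) %in% gids)))
      return(sprintf("%s names must be group ids", slotname))
  }
  if (length(object@category) &&
      !all(object@category %in% c("Kn", "Hy", "Un") | is.na(object@category)))
    return("category values must be Kn, Hy or Un")
  if (length(object@scope) &&
      !all(object@scope %in% c("shared", "unique") | is.na(object@scope)))
    return("scope values must be shared or unique")
  TRUE
})

#' SimilarityNetwork: complete weighted organism network
#'
#' Organisms are nodes of a complete undirected graph; edge weights are
#' pairwise similarities (functional-repertoire or whole-genome) stored
#' as fractions in [0, 1]. Internally a dense symmetric matrix with unit
#' diagonal; percentages appear only in rendered output.
#'
#' @slot sim symmetric numeric matrix with unit diagonal, entries in
#'   [0, 1], dimnames = organism ids.
#'
#' @seealso [buildSimilarityMatrix()], [singleLinkageClusters()]
#' @export
setClass("SimilarityNetwork", slots = c(sim = "matrix"))

setValidity("SimilarityNetwork", function(object) {
  s <- object@sim
  if (!is.numeric(s) || nrow(s) != ncol(s))
    return("sim must be a square numeric matrix")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    return("sim must carry identical organism row/col names")
  if (anyDuplicated(rownames(s))) return("duplicate organism ids")
  if (anyNA(s) || any(s < 0) || any(s > 1))
    return("similarities must lie in [0, 1]")
  if (!isTRUE(all.equal(s, t(s), tolerance = 1e-12)))
    return("sim must be symmetric")
  if (any(abs(diag(s) - 1) > 1e-12))
    return("diagonal must be 1 (an organism is identical to itself)")
  TRUE
})

#' ModulePartition: organism modules from resolution-tuned Louvain
#'
#' A total partition of the organisms of a complete similarity network
#' into modules, detected at a given resolution. Higher resolution values
#' yield larger, coarser (more functionally diverse) modules.
#'
#' @slot assignment named character vector mapping organism id to module id.
#' @slot resolution positive numeric coarseness parameter.
#' @slot seed integer seed that made the run deterministic.
#'
#' @seealso [louvainPartition()], [moduleTaxonomyJaccard()]
#' @export
setClass("ModulePartition",
  slots = c(assignment = "character", resolution = "numeric",
            seed = "integer"))

setValidity("ModulePartition", function(object) {
  a <- object@assignment
  if (length(a) == 0L || is.null(names(a)) || anyDuplicated(names(a)))
    return("assignment must map each organism exactly once")
  if (anyNA(a)) return("every organism must receive a module")
  if (length(object@resolution) != 1L || object@resolution <= 0)
    return("resolution must be a single positive number")
  TRUE
})

#' BipartiteNetwork: the organism-function ("plus") view
#'
#' Two node types, organisms and function groups; an edge links an
#' organism to every group of its functional repertoire. There is no
#' edge directly linking organism nodes, so organisms connect only
#' through shared functions.
#'
#' @slot organisms character vector of organism ids (always all included).
#' @slot functionGroups character vector of included group ids.
#' @slot edges data.frame with columns \code{organism}, \code{group}.
#' @slot category named character vector, category per included group.
#'
#' @seealso [buildFusionPlus()], [exclusiveSharedFunctions()]
#' @export
setClass("BipartiteNetwork",
  slots = c(organisms = "character", functionGroups = "character",
            edges = "data.frame", category = "character"))

setValidity("BipartiteNetwork", function(object) {
  e <- object@edges
  if (!all(c("organism", "group") %in% names(e)))
    return("edges must have columns organism, group")
  if (nrow(e)) {
    if (!all(e$organism %in% object@organisms))
      return("edge endpoints must be known organisms")
    if (!all(e$group %in% object@functionGroups))
      return("edge endpoints must be included groups")
    if (anyDuplicated(paste(e$organism, e$group, sep = "\r")))
      return("at most one edge per organism-group pair")
  }
  TRUE
})

#' LayeredHierarchy: stitched multi-layer single-linkage hierarchy
#'
#' Built by sweeping the similarity cut-off upward in fixed increments:
#' within every cluster at cut-off X, the clusters at the next cut-off
#' are related by a neighbor-joining tree over mean inter-cluster
#' similarities, and layers are stitched by substituting each cluster
#' node with its refinement subtree. The combined structure is a compact
#' visual representation of functional similarity; it is not a phylogeny
#' and does not directly convey evolutionary relationships.
#'
#' @slot tree an [ape::phylo] tree whose tips are organisms.
#' @slot cutoffs the similarity cut-offs (fractions) of the layers.
#' @slot memberships list, one named character vector per cut-off,
#'   mapping organism id to its single-linkage cluster id at that layer.
#'
#' @seealso [buildLayeredHierarchy()], [hierarchyCorrelation()]
#' @export
setClass("LayeredHierarchy",
  slots = c(tree = "ANY", cutoffs = "numeric", memberships = "list"))

setValidity("LayeredHierarchy", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be a phylo object")
  if (length(object@cutoffs) != length(object@memberships))
    return("one membership vector per cutoff required")
  TRUE
})
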