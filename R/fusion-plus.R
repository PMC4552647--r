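#' Build the bipartite organism-function network
#'
#' The "plus" view of a similarity network: organisms and function
#' groups are the two node types, and an organism is linked to every
#' group of its repertoire, so organism pairs are connected only
#' through the functions they share. A category filter restricts the
#' function nodes (e.g. only Kn, or Kn and Hy); organisms are always
#' included.
#'
#' @param repertoires named list organism id -> group-id vector, as
#'   from [buildRepertoires()].
#' @param groups a categorized [FunctionGroups-class] (used for the
#'   group categories), or a named character vector group id ->
#'   category.
#' @param include categories to keep; default all three.
#' @return a [BipartiteNetwork-class].
#' @export
buildFusionPlus <- function(repertoires, groups,
                            include = c("Kn", "Hy", "Un")) {
  stopifnot(length(repertoires) >= 1L)
  category <- if (is(groups, "FunctionGroups")) groupCategory(groups)
              else groups
  if (is.null(names(category)))
    stop("group categories must be named by group id")
  bad <- setdiff(include, c("Kn", "Hy", "Un"))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  keep <- names(category)[!is.na(category) & category %in% include]
  orgs <- sort(names(repertoires))
  edges <- do.call(rbind, lapply(orgs, function(o) {
    g <- intersect(unique(repertoires[[o]]), keep)
    if (!length(g)) return(NULL)
    data.frame(organism = o, group = sort(g), stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(organism = character(), group = character(),
                        stringsAsFactors = FALSE)
  used <- sort(unique(edges$group))
  if (!length(used))
    warning("category filter excludes every function group")
  new("BipartiteNetwork", organisms = orgs, functionGroups = used,
      edges = edges, category = category[used])
}

#' Function groups exclusive to a set of organisms
#'
#' Strict mode (default) returns the groups carried by every organism
#' of `inSet` and by none of `outSet` ("exclusive to and ubiquitous
#' in"); relaxed mode requires only that at least one `inSet` organism
#' carries the group ("shared by ... but not by ..."). With `inSet`
#' equal to all organisms and an empty `outSet`, strict mode yields the
#' core functions of the collection.
#'
#' @param network a [BipartiteNetwork-class].
#' @param inSet organisms whose common/present functions are sought.
#' @param outSet organisms that must not carry the returned functions;
#'   disjoint from `inSet`.
#' @param mode `"strict"` (default) or `"relaxed"`.
#' @return character vector of group ids.
#' @export
exclusiveSharedFunctions <- function(network, inSet, outSet = character(),
                                     mode = c("strict", "relaxed")) {
  stopifnot(is(network, "BipartiteNetwork"))
  mode <- match.arg(mode)
  if (length(intersect(inSet, outSet)))
    stop("inSet and outSet overlap: ",
         paste(intersect(inSet, outSet), collapse = ", "))
  unknown <- setdiff(c(inSet, outSet), network@organisms)
  if (length(unknown))
    stop("unknown organism(s): ", paste(unknown, collapse = ", "))
  if (!length(inSet)) stop("inSet must be non-empty")
  e <- network@edges
  carried <- split(e$group, e$organism)
  inLists <- lapply(inSet, function(o) carried[[o]])
  candidates <- if (mode == "strict") Reduce(intersect, inLists)
                else unique(unlist(inLists))
  if (!length(candidates)) return(character(0))
  outGroups <- unique(unlist(lapply(outSet, function(o) carried[[o]])))
  sort(setdiff(candidates, outGroups))
}

#' Sharing profile of function groups by category
#'
#' For each function node, its degree is the number of organisms
#' carrying it; the profile tabulates how many groups of each category
#' are shared by exactly n organisms. Widely shared functions tend to
#' be the annotated (Kn) ones, while Hy and Un functions tend to be
#' organism specific.
#'
#' @param network a categorized [BipartiteNetwork-class].
#' @return data.frame with columns `n_organisms`, `category`,
#'   `n_groups`; the `n_groups` total equals the number of function
#'   nodes.
#' @export
sharedFunctionCountProfile <- function(network) {
  stopifnot(is(network, "BipartiteNetwork"))
  e <- network@edges
  if (!nrow(e))
    return(data.frame(n_organisms = integer(), category = character(),
                      n_groups = integer()))
  deg <- table(e$group)
  cat_ <- network@category[names(deg)]
  dt <- data.table(n_organisms = as.integer(deg),
                   category = as.character(cat_))
  agg <- dt[, list(n_groups = .N), by = c("n_organisms", "category")]
  data.table::setorder(agg, n_organisms, category)
  as.data.frame(agg)
}
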