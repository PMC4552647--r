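#' Build per-organism functional repertoires
#'
#' An organism's functional repertoire is the set of function groups
#' containing at least one of its proteins. In-paralogs (several
#' proteins of one organism in the same group) collapse into a single
#' repertoire entry, so the repertoire size is at most the proteome
#' size.
#'
#' @param groups a [FunctionGroups-class].
#' @param proteinOrganism named character vector protein id ->
#'   organism id covering every clustered protein.
#' @return named list organism id -> character vector of group ids.
#' @export
buildRepertoires <- function(groups, proteinOrganism) {
  stopifnot(is(groups, "FunctionGroups"))
  m <- proteinGroups(groups)
  miss <- setdiff(names(m), names(proteinOrganism))
  if (length(miss))
    stop("protein(s) not mapped to an organism: ",
         paste(utils::head(miss, 5), collapse = ", "))
  org <- unname(proteinOrganism[names(m)])
  reps <- lapply(split(unname(m), org), function(g) sort(unique(g)))
  empty <- setdiff(unique(proteinOrganism), names(reps))
  if (length(empty))
    warning("organism(s) with zero proteins omitted: ",
            paste(empty, collapse = ", "))
  reps[order(names(reps))]
}

#' Functional repertoire similarity of two organisms
#'
#' The number of shared function groups divided by the bigger
#' repertoire size. Similar organisms are assumed to have similar
#' repertoire sizes, so a vast size difference itself indicates low
#' similarity; this is why the larger size, not the smaller, is the
#' denominator.
#'
#' @param a,b character vectors of function-group ids (repertoires).
#' @return similarity fraction in [0, 1].
#' @export
repertoireSimilarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("repertoires must be non-empty")
  length(intersect(a, b)) / max(length(a), length(b))
}

#' Whole-genome similarity baseline
#'
#' Sequence-identity analogue of the repertoire similarity, used to
#' compare function-based classification against plain gene content:
#' a protein is shared when it has an alignment at >= `minIdentity`
#' percent identity to any protein of the other organism (no alignment
#' length requirement). The shared count is the minimum of the two
#' directional counts (a conservative symmetric reading; both
#' directional counts are returned as attributes), normalised by the
#' bigger proteome size.
#'
#' @param proteinsA,proteinsB character vectors of protein ids of the
#'   two organisms.
#' @param hits alignment table (as from [readAlignmentTable()]) or
#'   consolidated identity pairs with columns `query`, `subject`,
#'   `identity`.
#' @param minIdentity percent identity cut-off for homology; default 40.
#' @return similarity fraction in [0, 1] with attributes `countAB`
#'   and `countBA` (directional shared-protein counts).
#' @export
wholeGenomeSimilarity <- function(proteinsA, proteinsB, hits,
                                  minIdentity = 40) {
  if (!length(proteinsA) || !length(proteinsB))
    stop("both proteomes must be non-empty")
  hits <- as.data.table(hits)
  if (!all(c("query", "subject", "identity") %in% names(hits)))
    stop("hits need columns query, subject, identity")
  hh <- hits[hits$identity >= minIdentity]
  inA <- c(hh$query[hh$subject %in% proteinsB &
                      hh$query %in% proteinsA],
           hh$subject[hh$query %in% proteinsB &
                        hh$subject %in% proteinsA])
  inB <- c(hh$query[hh$subject %in% proteinsA &
                      hh$query %in% proteinsB],
           hh$subject[hh$query %in% proteinsA &
                        hh$subject %in% proteinsB])
  countAB <- length(unique(inA))
  countBA <- length(unique(inB))
  out <- min(countAB, countBA) /
    max(length(unique(proteinsA)), length(unique(proteinsB)))
  attr(out, "countAB") <- countAB
  attr(out, "countBA") <- countBA
  out
}

#' Build the complete organism similarity network
#'
#' Computes the functional repertoire similarity for every unordered
#' organism pair (each pair once; the matrix is symmetric with unit
#' diagonal by construction). Implemented as a sparse incidence
#' cross-product, so a thousand-organism network takes seconds.
#'
#' @param repertoires named list organism id -> group-id vector, as
#'   from [buildRepertoires()].
#' @return a [SimilarityNetwork-class].
#' @export
buildSimilarityMatrix <- function(repertoires) {
  if (length(repertoires) < 2L) stop("need at least 2 organisms")
  orgs <- names(repertoires)
  if (is.null(orgs) || anyDuplicated(orgs))
    stop("repertoires must be uniquely named by organism id")
  repertoires <- lapply(repertoires, function(g) unique(as.character(g)))
  sizes <- lengths(repertoires)
  if (any(sizes == 0L)) stop("empty repertoire for: ",
                             paste(orgs[sizes == 0L], collapse = ", "))
  gids <- sort(unique(unlist(repertoires, use.names = FALSE)))
  i <- rep(seq_along(repertoires), lengths(repertoires))
  j <- match(unlist(repertoires, use.names = FALSE), gids)
  inc <- sparseMatrix(i = i, j = j, x = 1,
                      dims = c(length(orgs), length(gids)))
  shared <- as.matrix(Matrix::tcrossprod(inc))
  denom <- outer(sizes, sizes, pmax)
  s <- shared / denom
  diag(s) <- 1
  dimnames(s) <- list(orgs, orgs)
  new("SimilarityNetwork", sim = s)
}

#' Construct a SimilarityNetwork from a raw matrix
#'
#' Convenience constructor with validation (symmetry, unit diagonal,
#' entries in [0, 1]).
#'
#' @param sim named symmetric numeric matrix.
#' @return a [SimilarityNetwork-class].
#' @export
SimilarityNetwork <- function(sim) new("SimilarityNetwork", sim = sim)
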