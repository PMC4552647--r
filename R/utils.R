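# Evaluate an expression under a temporary RNG seed, restoring the
# caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic module/cluster ids ranked by smallest member.
.rankedIds <- function(membership, prefix) {
  firsts <- vapply(split(names(membership), membership), min, character(1))
  ranks <- rank(firsts, ties.method = "first")
  width <- max(3L, nchar(length(firsts)))
  stats::setNames(
    sprintf("%s%0*d", prefix, width, ranks[match(membership,
                                                 names(firsts))]),
    names(membership))
}

# Number of co-assigned (same-cluster) unordered pairs in a partition.
.coassignedPairs <- function(partition) {
  sizes <- table(partition)
  sum(choose(as.numeric(sizes), 2))
}
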