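#' Pair similarities with same-taxon labels
#'
#' Flattens a similarity network into one row per unordered organism
#' pair with the pair's similarity and whether the two organisms share
#' the taxon at the given level. Pairs involving an organism without a
#' taxon at the level are excluded and reported via the
#' `excludedOrganisms` attribute.
#'
#' @param network a [SimilarityNetwork-class].
#' @param taxonomy data.frame as from [readTaxonomy()].
#' @param level one of [TAXONOMY_RANKS].
#' @return data.frame with columns `org_a`, `org_b`, `similarity`,
#'   `sameTaxon`.
#' @export
pairwiseLabels <- function(network, taxonomy, level) {
  stopifnot(is(network, "SimilarityNetwork"))
  s <- similarityMatrix(network)
  orgs <- rownames(s)
  taxa <- .levelTaxa(taxonomy, level, orgs)
  excluded <- orgs[is.na(taxa)]
  keep <- orgs[!is.na(taxa)]
  s <- s[keep, keep, drop = FALSE]
  taxa <- taxa[keep]
  idx <- which(lower.tri(s), arr.ind = TRUE)
  out <- data.frame(org_a = keep[idx[, 2L]], org_b = keep[idx[, 1L]],
                    similarity = s[idx],
                    sameTaxon = taxa[idx[, 2L]] == taxa[idx[, 1L]],
                    row.names = NULL)
  attr(out, "excludedOrganisms") <- excluded
  out
}

.confusion <- function(similarity, sameTaxon, threshold) {
  pred <- similarity >= threshold
  TP <- sum(pred & sameTaxon)
  FP <- sum(pred & !sameTaxon)
  FN <- sum(!pred & sameTaxon)
  TN <- sum(!pred & !sameTaxon)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       PA = if (TP + FP > 0) TP / (TP + FP) else NA_real_,
       PC = if (TP + FN > 0) TP / (TP + FN) else NA_real_)
}

#' Confusion counts of pairwise taxonomy assignment at a threshold
#'
#' Organism pairs with similarity >= `threshold` are predicted to share
#' the taxon at `level`. Counted against the reference taxonomy this
#' gives TP/FP/TN/FN, the positive accuracy PA = TP/(TP+FP)
#' (precision) and the positive coverage PC = TP/(TP+FN) (recall).
#' PA or PC is NA when its denominator is zero.
#'
#' @inheritParams pairwiseLabels
#' @param threshold similarity fraction in [0, 1].
#' @return list with `TP`, `FP`, `TN`, `FN`, `PA`, `PC`.
#' @export
pairwiseConfusion <- function(network, taxonomy, level, threshold) {
  pl <- pairwiseLabels(network, taxonomy, level)
  out <- .confusion(pl$similarity, pl$sameTaxon, threshold)
  out$excludedOrganisms <- attr(pl, "excludedOrganisms")
  out
}

.prAuc <- function(similarity, sameTaxon) {
  if (all(sameTaxon) || !any(sameTaxon))
    stop("degenerate labels: all pairs are of one class")
  thr <- sort(unique(similarity), decreasing = TRUE)
  pts <- lapply(thr, function(t) {
    cc <- .confusion(similarity, sameTaxon, t)
    data.frame(threshold = t, PA = cc$PA, PC = cc$PC)
  })
  curve <- do.call(rbind, pts)
  curve <- curve[!is.na(curve$PA), , drop = FALSE]
  # anchor the curve at PC = 0 with the most stringent defined PA
  pc <- c(0, curve$PC)
  pa <- c(curve$PA[1L], curve$PA)
  auc <- sum(diff(pc) * (utils::head(pa, -1) + utils::tail(pa, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Precision/recall curve and AUC of a similarity metric
#'
#' Sweeps the threshold over all distinct pair similarities, computes
#' (PC, PA) at each, drops points with undefined PA (no predicted
#' positives) and integrates by the trapezoid rule over PC, anchoring
#' the curve at PC = 0. The AUC depends only on the ranking of the
#' similarities, so it is invariant under strictly monotone transforms.
#'
#' @inheritParams pairwiseLabels
#' @return list with `curve` (data.frame threshold/PA/PC) and `auc`.
#' @export
prCurveAuc <- function(network, taxonomy, level) {
  pl <- pairwiseLabels(network, taxonomy, level)
  .prAuc(pl$similarity, pl$sameTaxon)
}

#' Bootstrap distribution of the precision/recall AUC
#'
#' Resamples a fraction of the evaluation units with replacement
#' `reps` times and recomputes the AUC each time. The unit is the
#' organism pair (what the confusion counts are built from) by
#' default; resampling whole organisms (taking the induced pairs) is
#' available as an alternative reading. Replicates whose resample
#' contains a single label class get an NA AUC.
#'
#' @inheritParams pairwiseLabels
#' @param fraction fraction of units drawn per replicate; default 0.10.
#' @param reps number of replicates; default 100.
#' @param seed integer seed making the replicate set reproducible.
#' @param unit `"pairs"` (default) or `"organisms"`.
#' @return numeric vector of `reps` AUC values.
#' @export
bootstrapAuc <- function(network, taxonomy, level, fraction = 0.10,
                         reps = 100L, seed = 1L,
                         unit = c("pairs", "organisms")) {
  unit <- match.arg(unit)
  stopifnot(fraction > 0, fraction <= 1, reps >= 1)
  pl <- pairwiseLabels(network, taxonomy, level)
  orgs <- unique(c(pl$org_a, pl$org_b))
  .withSeed(as.integer(seed), {
    vapply(seq_len(reps), function(r) {
      if (unit == "pairs") {
        m <- max(1L, round(fraction * nrow(pl)))
        take <- sample.int(nrow(pl), m, replace = TRUE)
        sub <- pl[take, ]
      } else {
        m <- max(2L, round(fraction * length(orgs)))
        who <- unique(sample(orgs, m, replace = TRUE))
        sub <- pl[pl$org_a %in% who & pl$org_b %in% who, ]
      }
      if (nrow(sub) == 0L || all(sub$sameTaxon) || !any(sub$sameTaxon))
        return(NA_real_)
      .prAuc(sub$similarity, sub$sameTaxon)$auc
    }, numeric(1))
  })
}

#' Compare two bootstrap AUC distributions
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) between two AUC distributions, e.g. from two different
#' similarity metrics evaluated at the same taxonomy level.
#'
#' @param aucA,aucB numeric vectors (NAs dropped) of length >= 2.
#' @return list with `statistic` (rank-sum W) and `p.value`.
#' @export
compareMetrics <- function(aucA, aucB) {
  aucA <- aucA[!is.na(aucA)]
  aucB <- aucB[!is.na(aucB)]
  if (length(aucA) < 2L || length(aucB) < 2L)
    stop("need at least 2 values per distribution")
  wt <- suppressWarnings(
    stats::wilcox.test(aucA, aucB, alternative = "two.sided",
                       exact = FALSE, correct = FALSE))
  p <- wt$p.value
  # all observations tied across both samples: no evidence of a shift
  if (is.nan(p)) p <- 1
  list(statistic = unname(wt$statistic), p.value = p)
}
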