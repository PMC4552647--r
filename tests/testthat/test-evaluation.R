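# A small block network with separated similarity ranges doubles as a
# perfectly separating metric: same-taxon pairs ~0.9, others ~0.05.
perfectInstance <- function(sizes = c(5L, 5L), jitter = 0) {
  bn <- generateBlockNetwork(sizes, intraMean = 0.9, interMean = 0.05,
                             jitterSd = jitter, seed = 77)
  list(network = bn$network, taxonomy = flatTaxonomy(bn$partition))
}

test_that("confusion counts behave at the threshold extremes", {
  pi_ <- perfectInstance()
  cc <- pairwiseConfusion(pi_$network, pi_$taxonomy, "species", 0.5)
  expect_equal(cc$PA, 1.0)
  expect_equal(cc$PC, 1.0)
  expect_equal(cc$FP + cc$FN, 0)
  # threshold 0 predicts every pair positive
  cc0 <- pairwiseConfusion(pi_$network, pi_$taxonomy, "species", 0)
  expect_equal(cc0$PC, 1.0)
  nPairs <- cc0$TP + cc0$FP
  expect_equal(cc0$PA, cc0$TP / nPairs)
  expect_equal(nPairs, choose(10, 2))
})

test_that("confusion counts match an exhaustive 45-pair oracle", {
  set.seed(33)
  orgs <- sprintf("o%02d", 1:10)
  s <- matrix(runif(100), 10, 10, dimnames = list(orgs, orgs))
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  net <- SimilarityNetwork(s)
  taxa <- stats::setNames(sample(c("X", "Y"), 10, replace = TRUE), orgs)
  tax <- flatTaxonomy(taxa)
  for (thr in c(0.2, 0.5, 0.8)) {
    cc <- pairwiseConfusion(net, tax, "species", thr)
    TP <- FP <- TN <- FN <- 0L
    for (i in 1:10) for (j in seq_len(i - 1)) {
      pred <- s[i, j] >= thr
      same <- taxa[[i]] == taxa[[j]]
      if (pred && same) TP <- TP + 1L
      if (pred && !same) FP <- FP + 1L
      if (!pred && same) FN <- FN + 1L
      if (!pred && !same) TN <- TN + 1L
    }
    expect_equal(cc[c("TP", "FP", "TN", "FN")],
                 list(TP = TP, FP = FP, TN = TN, FN = FN))
  }
})

test_that("a perfectly separating similarity gives AUC 1", {
  pi_ <- perfectInstance()
  out <- prCurveAuc(pi_$network, pi_$taxonomy, "species")
  expect_equal(out$auc, 1.0)
})

test_that("AUC matches a hand-computed trapezoid on a tiny instance", {
  orgs <- c("a", "b", "c", "d")
  s <- matrix(0, 4, 4, dimnames = list(orgs, orgs))
  s["a", "b"] <- s["b", "a"] <- 0.9   # same taxon
  s["a", "c"] <- s["c", "a"] <- 0.7   # different
  s["b", "c"] <- s["c", "b"] <- 0.5   # different
  s["a", "d"] <- s["d", "a"] <- 0.4   # same
  s["b", "d"] <- s["d", "b"] <- 0.2   # same
  s["c", "d"] <- s["d", "c"] <- 0.1   # different
  diag(s) <- 1
  tax <- flatTaxonomy(c(a = "X", b = "X", c = "Y", d = "X"))
  out <- prCurveAuc(SimilarityNetwork(s), tax, "species")
  # thresholds (desc): 0.9,0.7,0.5,0.4,0.2,0.1 ->
  # (PC,PA): (1/3,1),(1/3,1/2),(1/3,1/3),(2/3,1/2),(1,3/5),(1,1/2)
  pc <- c(0, 1/3, 1/3, 1/3, 2/3, 1, 1)
  pa <- c(1, 1, 1/2, 1/3, 1/2, 3/5, 1/2)
  want <- sum(diff(pc) * (head(pa, -1) + tail(pa, -1)) / 2)
  expect_equal(out$auc, want)
  expect_equal(nrow(out$curve), 6L)
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(44)
  orgs <- sprintf("o%02d", 1:12)
  s <- matrix(runif(144, 0.01, 0.99), 12, 12, dimnames = list(orgs, orgs))
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  tax <- flatTaxonomy(stats::setNames(
    sample(c("X", "Y"), 12, replace = TRUE), orgs))
  a1 <- prCurveAuc(SimilarityNetwork(s), tax, "species")$auc
  s2 <- s^3  # strictly monotone on [0,1]
  diag(s2) <- 1
  a2 <- prCurveAuc(SimilarityNetwork(s2), tax, "species")$auc
  expect_equal(a1, a2)
})

test_that("PC is non-increasing in the threshold", {
  set.seed(46)
  pi_ <- perfectInstance(jitter = 0.15)
  thr <- seq(0, 1, by = 0.05)
  pcs <- vapply(thr, function(t)
    pairwiseConfusion(pi_$network, pi_$taxonomy, "species", t)$PC,
    numeric(1))
  expect_true(all(diff(pcs) <= 1e-12))
})

test_that("label-independent similarity gives AUC near the base rate", {
  set.seed(55)
  n <- 40
  orgs <- sprintf("o%02d", 1:n)
  s <- matrix(runif(n * n), n, n, dimnames = list(orgs, orgs))
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  diag(s) <- 1
  taxa <- stats::setNames(rep(c("X", "Y"), each = n / 2), orgs)
  out <- prCurveAuc(SimilarityNetwork(s), flatTaxonomy(taxa), "species")
  base <- (2 * choose(n / 2, 2)) / choose(n, 2)
  expect_lt(abs(out$auc - base), 0.05)
})

test_that("degenerate single-class labels raise an error", {
  pi_ <- perfectInstance(c(4L))
  tax <- flatTaxonomy(stats::setNames(
    rep("X", 4), organisms(pi_$network)))
  expect_error(prCurveAuc(pi_$network, tax, "species"), "degenerate")
})

test_that("bootstrap AUC is reproducible and correct on perfect data", {
  pi_ <- perfectInstance()
  b1 <- bootstrapAuc(pi_$network, pi_$taxonomy, "species", reps = 50,
                     seed = 7)
  b2 <- bootstrapAuc(pi_$network, pi_$taxonomy, "species", reps = 50,
                     seed = 7)
  expect_identical(b1, b2)
  expect_length(b1, 50L)
  expect_true(all(b1[!is.na(b1)] == 1.0))
  # organism-unit resampling is also available and reproducible
  o1 <- bootstrapAuc(pi_$network, pi_$taxonomy, "species", reps = 20,
                     seed = 7, unit = "organisms")
  expect_length(o1, 20L)
})

test_that("bootstrap mean tracks the full-data AUC on noisy planted data", {
  pi_ <- perfectInstance(c(8L, 8L), jitter = 0.25)
  full <- prCurveAuc(pi_$network, pi_$taxonomy, "species")$auc
  b <- bootstrapAuc(pi_$network, pi_$taxonomy, "species", reps = 100,
                    seed = 11)
  b <- b[!is.na(b)]
  expect_gt(length(b), 80)
  expect_lt(abs(mean(b) - full), 2 * stats::sd(b))
})

test_that("rank-sum comparison behaves at the null and at separation", {
  x <- rep(c(0.80, 0.85, 0.90), 20)
  same <- compareMetrics(x, x)
  expect_gte(same$p.value, 0.99)
  lo <- runif(100, 0, 0.4)
  hi <- runif(100, 0.6, 1)
  sep <- compareMetrics(lo, hi)
  expect_lt(sep$p.value, 1e-10)
  expect_error(compareMetrics(1, c(1, 2)), "at least 2")
})

test_that("the normal-approximation p agrees with exact enumeration on small tie-free data", {
  set.seed(60)
  x <- c(0.11, 0.23, 0.35, 0.47, 0.59, 0.71)
  y <- c(0.17, 0.29, 0.41, 0.53, 0.65, 0.77)
  approx <- compareMetrics(x, y)$p.value
  exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  expect_gt(approx, 0.5)
  expect_gt(exact, 0.5)
  shifted <- compareMetrics(x, y + 10)
  exactShift <- stats::wilcox.test(x, y + 10, exact = TRUE)$p.value
  expect_lt(shifted$p.value, 0.05)
  expect_lt(exactShift, 0.05)
})
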