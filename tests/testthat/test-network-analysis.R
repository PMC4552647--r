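test_that("single linkage components follow the cut-off", {
  net <- pairNetwork(c("a", "b", "c"),
                     list(list("a", "b", 0.5), list("b", "c", 0.3)))
  expect_length(unique(singleLinkageClusters(net, 0)), 1L)
  p <- singleLinkageClusters(net, 0.4)
  expect_equal(p[["a"]], p[["b"]])
  expect_false(p[["c"]] == p[["a"]])
  expect_length(unique(singleLinkageClusters(net, 0.95)), 3L)
})

test_that("single-linkage partitions nest as the cut-off rises", {
  bn <- generateBlockNetwork(c(6L, 6L, 6L), jitterSd = 0.05, seed = 10)
  cuts <- seq(0.05, 1, by = 0.05)
  parts <- lapply(cuts, function(co) singleLinkageClusters(bn$network, co))
  for (k in seq_along(cuts)[-1]) {
    fine <- parts[[k]]
    coarse <- parts[[k - 1]]
    # every cluster at the higher cut-off sits inside one coarser cluster
    for (cl in unique(fine)) {
      members <- names(fine)[fine == cl]
      expect_length(unique(coarse[members]), 1L)
    }
  }
})

test_that("overall accuracy implements majority assignment", {
  tax <- flatTaxonomy(c(o1 = "X", o2 = "X", o3 = "Y"))
  part <- c(o1 = "c1", o2 = "c1", o3 = "c1")
  expect_equal(as.numeric(overallAccuracy(part, tax, "species")), 2 / 3)
  # pure clusters give accuracy 1 at every level
  part <- c(o1 = "c1", o2 = "c1", o3 = "c2")
  expect_equal(as.numeric(overallAccuracy(part, tax, "genus")), 1.0)
})

test_that("accuracy ties are scored per the configured rule", {
  tax <- flatTaxonomy(c(o1 = "X", o2 = "Y"))
  part <- c(o1 = "c1", o2 = "c1")
  expect_equal(as.numeric(overallAccuracy(part, tax, "species")), 1 / 2)
  expect_equal(as.numeric(
    overallAccuracy(part, tax, "species", tieBreak = "either")), 1.0)
})

test_that("organisms without a taxon are excluded and reported", {
  tax <- makeTaxonomy(list(o1 = c(species = "X"), o2 = c(species = "X"),
                           o3 = c(genus = "G")))
  part <- c(o1 = "c1", o2 = "c1", o3 = "c1")
  acc <- overallAccuracy(part, tax, "species")
  expect_equal(as.numeric(acc), 1.0)
  expect_equal(attr(acc, "excluded"), "o3")
})

test_that("accuracy matches a brute-force per-cluster majority oracle", {
  set.seed(37)
  for (rep in 1:10) {
    orgs <- sprintf("o%02d", 1:20)
    part <- stats::setNames(sample(c("c1", "c2", "c3"), 20, replace = TRUE),
                            orgs)
    tax <- flatTaxonomy(stats::setNames(
      sample(c("X", "Y", "Z"), 20, replace = TRUE), orgs))
    got <- as.numeric(overallAccuracy(part, tax, "species"))
    taxa <- stats::setNames(tax$species, tax$organism_id)
    correct <- 0
    for (cl in unique(part)) {
      members <- names(part)[part == cl]
      correct <- correct + max(table(taxa[members]))
    }
    expect_equal(got, correct / 20)
  }
})

test_that("taxon coverage matches the worked 4-of-7 example", {
  orgs <- sprintf("x%d", 1:9)
  part <- stats::setNames(
    c("cA", "cA", "cA", "cA", "cB", "cB", "cC", "cD", "cD"), orgs)
  tax <- flatTaxonomy(stats::setNames(
    c(rep("X", 7), "Y", "Y"), orgs))
  cov <- taxonCoverage(part, tax, "species")
  expect_equal(unname(cov$perTaxon["X"]), 4 / 7)
  expect_equal(unname(cov$majorCluster["X"]), "cA")
  expect_equal(unname(cov$perTaxon["Y"]), 1.0)
  expect_equal(cov$overall, 1 / 2)  # only Y is fully contained
})

test_that("overall coverage counts only multi-member taxa", {
  part <- c(o1 = "c1", o2 = "c2", o3 = "c2")
  tax <- flatTaxonomy(c(o1 = "X", o2 = "Y", o3 = "Y"))
  cov <- taxonCoverage(part, tax, "species")
  expect_equal(cov$overall, 1.0)   # singleton taxon X excluded
})

test_that("coverage matches a brute-force max-over-clusters oracle", {
  set.seed(41)
  for (rep in 1:10) {
    orgs <- sprintf("o%02d", 1:25)
    part <- stats::setNames(sample(sprintf("c%d", 1:5), 25, replace = TRUE),
                            orgs)
    tax <- flatTaxonomy(stats::setNames(
      sample(c("T1", "T2", "T3", "T4"), 25, replace = TRUE), orgs))
    cov <- taxonCoverage(part, tax, "species")
    taxa <- stats::setNames(tax$species, tax$organism_id)
    for (tx in unique(taxa)) {
      members <- names(taxa)[taxa == tx]
      expect_equal(unname(cov$perTaxon[tx]),
                   max(table(part[members])) / length(members))
    }
  }
})

test_that("the cut-off sweep shows the expected accuracy/coverage trends", {
  d <- generateSyntheticDataset(syntheticConfig(seed = 3))
  reps <- d$groundTruth$repertoires
  net <- buildSimilarityMatrix(reps)
  sw <- sweepCutoffs(net, d$taxonomy, cutoffs = seq(0.05, 1, by = 0.05))
  for (lev in TAXONOMY_RANKS) {
    sl <- sw[sw$level == lev, ]
    sl <- sl[order(sl$cutoff), ]
    expect_true(all(diff(sl$overall_accuracy) >= -1e-12))
    expect_true(all(diff(sl$overall_coverage) <= 1e-12))
  }
  # at cut-off 1.0 all repertoires are distinct -> singletons, accuracy 1
  top <- sw[sw$cutoff == 1 & sw$level == "species", ]
  expect_equal(top$overall_accuracy, 1.0)
  expect_equal(top$n_clusters, nrow(d$taxonomy))
  # single-cutoff grid gives a single row per level
  one <- sweepCutoffs(net, d$taxonomy, cutoffs = 0.5, levels = "genus")
  expect_equal(nrow(one), 1L)
})

test_that("concordance bounds bracket the designed separating cut-offs", {
  d <- generateSyntheticDataset(syntheticConfig(seed = 4))
  net <- buildSimilarityMatrix(d$groundTruth$repertoires)
  dc <- d$groundTruth$designedCutoffs
  sw <- sweepCutoffs(net, d$taxonomy, cutoffs = sort(unique(dc)))
  for (lev in TAXONOMY_RANKS) {
    row <- sw[sw$level == lev & abs(sw$cutoff - dc[[lev]]) < 1e-9, ]
    expect_equal(row$overall_accuracy, 1.0, info = lev)
    expect_equal(row$overall_coverage, 1.0, info = lev)
  }
  b <- concordanceBounds(sw)
  expect_true(all(b$lower_bound <= b$upper_bound))
})

test_that("the layered hierarchy separates pairs before members", {
  orgs <- c("a1", "a2", "b1", "b2")
  s <- matrix(0.1, 4, 4, dimnames = list(orgs, orgs))
  s["a1", "a2"] <- s["a2", "a1"] <- 0.9
  s["b1", "b2"] <- s["b2", "b1"] <- 0.9
  diag(s) <- 1
  h <- buildLayeredHierarchy(SimilarityNetwork(s), increment = 0.05)
  d <- leafStepsOracle(hierarchyTree(h))
  expect_lt(d["a1", "a2"], d["a1", "b1"])
  expect_lt(d["b1", "b2"], d["a2", "b2"])
})

test_that("hierarchy layers refine monotonically", {
  bn <- generateBlockNetwork(c(4L, 4L, 4L), jitterSd = 0.03, seed = 6)
  h <- buildLayeredHierarchy(bn$network, increment = 0.05)
  mem <- h@memberships
  for (k in seq_along(mem)[-1]) {
    for (cl in unique(mem[[k]])) {
      members <- names(mem[[k]])[mem[[k]] == cl]
      expect_length(unique(mem[[k - 1]][members]), 1L)
    }
  }
  # every organism appears exactly once as a leaf
  expect_setequal(hierarchyTree(h)$tip.label, organisms(bn$network))
  expect_equal(length(hierarchyTree(h)$tip.label), 12L)
})

test_that("identical organisms stay in one cluster below 100%", {
  orgs <- c("u", "v", "w")
  s <- matrix(1, 3, 3, dimnames = list(orgs, orgs))
  h <- buildLayeredHierarchy(SimilarityNetwork(s), increment = 0.1)
  for (m in h@memberships) expect_length(unique(m), 1L)
  expect_setequal(hierarchyTree(h)$tip.label, orgs)
})

test_that("hierarchy correlation is exact for identical trees and matches the oracle", {
  bn <- generateBlockNetwork(c(4L, 4L), jitterSd = 0.05, seed = 12)
  h <- buildLayeredHierarchy(bn$network, increment = 0.1)
  expect_equal(hierarchyCorrelation(h, h), 1.0)
  # balanced-vs-caterpillar with scrambled labels: correlation must
  # match brute-force path counting (a pure star has zero distance
  # variance, so a balanced tree is the non-degenerate analogue)
  bal <- ape::read.tree(text = "(((t1:1,t2:1):1,t3:1):1,(t4:1,t5:1):1);")
  cat_ <- ape::read.tree(text = "((((t5:1,t3:1):1,t1:1):1,t4:1):1,t2:1);")
  got <- hierarchyCorrelation(bal, cat_)
  d1 <- leafStepsOracle(bal)
  d2 <- leafStepsOracle(cat_)
  ord <- sort(bal$tip.label)
  want <- stats::cor(d1[ord, ord][lower.tri(d1)],
                     d2[ord, ord][lower.tri(d2)])
  expect_equal(got, want)
  expect_gte(got, -1)
  expect_lte(got, 1)
  # spearman flag
  expect_equal(hierarchyCorrelation(bal, cat_, method = "spearman"),
               stats::cor(d1[ord, ord][lower.tri(d1)],
                          d2[ord, ord][lower.tri(d2)],
                          method = "spearman"))
})

test_that("hierarchy correlation rejects mismatched leaf sets", {
  t1 <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  t2 <- ape::read.tree(text = "((a:1,b:1):1,d:1);")
  expect_error(hierarchyCorrelation(t1, t2), "c.*d|d.*c")
})
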