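test_that("protein categorization follows the trigger rules", {
  cases <- list(
    list("putative membrane transporter", "hypothetical"),
    list("Hypothetical protein YacL", "hypothetical"),
    list("protein", "hypothetical"),
    list("  PROTEIN  ", "hypothetical"),
    list("Uncharacterized protein conserved in bacteria", "hypothetical"),
    list("uncharacterized PROTEIN conserved in Bacteria", "hypothetical"),
    list("DNA polymerase III subunit alpha", "known"),
    list("ATP synthase F1 subcomplex", "known"),
    list(NA_character_, "unknown"),
    list("", "unknown"),
    list("   ", "unknown"))
  for (cs in cases)
    expect_equal(categorizeProtein(cs[[1]]), cs[[2]], info = cs[[1]])
  # substring vs whole-word matching for the trigger terms
  expect_equal(categorizeProtein("computative regulator"), "hypothetical")
  expect_equal(categorizeProtein("computative regulator", wholeWord = TRUE),
               "known")
})

test_that("group categories follow the Kn > Hy > Un precedence", {
  memb <- c(a = "g1", b = "g1", c = "g2", d = "g2", e = "g3", f = "g3")
  fg <- new("FunctionGroups", membership = memb,
            category = character(0), scope = character(0))
  pc <- c(a = "known", b = "unknown", c = "hypothetical",
          d = "unknown", e = "unknown", f = "unknown")
  out <- groupCategory(categorizeGroups(fg, pc))
  expect_equal(unname(out[c("g1", "g2", "g3")]), c("Kn", "Hy", "Un"))
  expect_error(categorizeGroups(fg, pc[-1]), "missing a category")
})

test_that("adding a known member never moves a group away from Kn", {
  set.seed(8)
  rank_ <- c(Un = 1, Hy = 2, Kn = 3)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    ids <- sprintf("p%d", seq_len(n + 1))
    memb <- stats::setNames(rep("g", n + 1), ids)
    pc <- stats::setNames(
      sample(c("known", "hypothetical", "unknown"), n, replace = TRUE),
      ids[1:n])
    before <- new("FunctionGroups",
                  membership = memb[1:n],
                  category = character(0), scope = character(0))
    after <- new("FunctionGroups", membership = memb,
                 category = character(0), scope = character(0))
    cb <- groupCategory(categorizeGroups(before, pc))[["g"]]
    ca <- groupCategory(categorizeGroups(
      after, c(pc, stats::setNames("known", ids[n + 1]))))[["g"]]
    expect_gte(rank_[[ca]], rank_[[cb]])
    expect_equal(ca, "Kn")
  }
})

test_that("scope tagging matches an organism-count oracle", {
  memb <- c(a1 = "g1", a2 = "g1", b1 = "g2", a3 = "g2", a4 = "g3",
            a5 = "g3")
  org <- c(a1 = "A", a2 = "B", b1 = "B", a3 = "B", a4 = "A", a5 = "A")
  fg <- new("FunctionGroups", membership = memb,
            category = character(0), scope = character(0))
  out <- groupScope(tagScope(fg, org))
  expect_equal(unname(out[c("g1", "g2", "g3")]),
               c("shared", "unique", "unique"))  # g3: two in-paralogs of A
  expect_error(tagScope(fg, org[-1]), "not mapped")
  # random partitions vs brute-force unique-organism counting
  set.seed(14)
  for (rep in 1:10) {
    prot <- sprintf("p%02d", 1:30)
    memb <- stats::setNames(sample(sprintf("g%d", 1:8), 30, replace = TRUE),
                            prot)
    org <- stats::setNames(sample(c("O1", "O2", "O3"), 30, replace = TRUE),
                           prot)
    fg <- new("FunctionGroups", membership = memb,
              category = character(0), scope = character(0))
    got <- groupScope(tagScope(fg, org))
    for (g in unique(memb)) {
      norg <- length(unique(org[names(memb)[memb == g]]))
      expect_equal(unname(got[g]), if (norg > 1) "shared" else "unique")
    }
  }
})

test_that("category and scope counts partition the group set", {
  d <- generateSyntheticDataset(syntheticConfig(seed = 2))
  pm <- consolidateBestHits(d$hits)
  fg <- mclCluster(buildFunctionGraph(pm, proteins = d$proteins$protein_id))
  pann <- d$annotations[d$proteins$protein_id]
  names(pann) <- d$proteins$protein_id
  fg <- categorizeGroups(fg, stats::setNames(categorizeProtein(pann),
                                             names(pann)))
  fg <- tagScope(fg, stats::setNames(d$proteins$organism_id,
                                     d$proteins$protein_id))
  cc <- table(groupCategory(fg))
  sc <- table(groupScope(fg))
  expect_equal(sum(cc), nGroups(fg))
  expect_equal(sum(sc), nGroups(fg))
  # planted per-function categories map 1:1 onto recovered groups
  planted <- table(c(known = "Kn", hypothetical = "Hy",
                     unknown = "Un")[d$groundTruth$categories])
  expect_equal(as.integer(cc[c("Kn", "Hy", "Un")]),
               as.integer(planted[c("Kn", "Hy", "Un")]))
})

test_that("annotation consistency reports modal fractions", {
  memb <- c(p1 = "g1", p2 = "g1", p3 = "g1", p4 = "g2")
  fg <- new("FunctionGroups", membership = memb,
            category = c(g1 = "Kn", g2 = "Kn"), scope = character(0))
  ann <- c(p1 = "sugar kinase", p2 = "Sugar  kinase (EC 2.7.1.4)",
           p3 = "acetate permease", p4 = "lone annotation")
  out <- annotationConsistency(fg, ann)
  expect_equal(out$modal_fraction[out$group_id == "g1"], 2 / 3)
  expect_equal(out$modal_fraction[out$group_id == "g2"], 1.0)
})

test_that("planted annotation purity shows up as the modal fraction", {
  n <- 100
  memb <- stats::setNames(rep("g1", n), sprintf("p%03d", 1:n))
  fg <- new("FunctionGroups", membership = memb,
            category = c(g1 = "Kn"), scope = character(0))
  ann <- stats::setNames(
    c(rep("citrate synthase", 90), rep("citrate synthase isoform", 10)),
    names(memb))
  out <- annotationConsistency(fg, ann)
  expect_equal(out$modal_fraction, 0.9)
  expect_equal(out$n_annotated, 100L)
})

test_that("annotation normalisation unifies cosmetic variants", {
  expect_equal(normalizeAnnotation("  Sugar   Kinase  "), "sugar kinase")
  expect_equal(normalizeAnnotation("sugar kinase (EC 2.7.1.4)"),
               "sugar kinase")
  expect_equal(normalizeAnnotation("sugar kinase EC 2.7.1.4"),
               "sugar kinase")
  expect_equal(normalizeAnnotation("EC-independent ligase"),
               "ec-independent ligase")
})
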