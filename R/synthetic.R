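#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the statistical structure the pipeline
#' assumes: a balanced taxonomy in which every taxon at every level
#' contributes a core pool of functions shared by all organisms below
#' it (phylum core down to species core), plus organism-unique
#' functions -- mirroring the observation that widely shared functions
#' are the annotated ones while unannotated functions tend to be
#' organism specific. Alignment hits are fabricated backwards from
#' target HSSP distances so that same-function protein pairs score at
#' or above the function-identity threshold and different-function
#' pairs score below it, with configurable noise.
#'
#' @param seed integer; a fixed seed makes all outputs identical.
#' @param nPhyla,classesPerPhylum,ordersPerClass,familiesPerOrder,generaPerFamily,speciesPerGenus
#'   branching factors of the balanced taxonomy.
#' @param organismsPerSpecies organisms (strains) per species.
#' @param corePoolSizes named integer vector (names = [TAXONOMY_RANKS])
#'   of new functions contributed by each taxon at each level.
#' @param uniqueFunctionRate target fraction of an organism's
#'   repertoire made of organism-unique functions.
#' @param annotationRates named fractions (known/hypothetical/unknown)
#'   summing to 1; per-function category probabilities.
#' @param annotationPurity fraction of a known function's annotated
#'   proteins carrying the modal annotation string (others get a
#'   cosmetic variant).
#' @param paralogRate probability that an organism carries a second
#'   in-paralog copy of a function.
#' @param identityJitterSd standard deviation (percent identity) of
#'   Gaussian noise added to fabricated identities; 0 = noise-free.
#' @param spuriousHitRate number of spurious (different-function,
#'   sub-threshold) hits as a fraction of true hits.
#' @param withSequences also fabricate random amino-acid sequences
#'   (only needed for FASTA round-trips; the pipeline never reads them).
#' @return validated config list.
#' @export
syntheticConfig <- function(seed = 1L,
                            nPhyla = 2L,
                            classesPerPhylum = 1L,
                            ordersPerClass = 1L,
                            familiesPerOrder = 2L,
                            generaPerFamily = 1L,
                            speciesPerGenus = 2L,
                            organismsPerSpecies = 2L,
                            corePoolSizes = c(species = 6L, genus = 8L,
                                              family = 10L, order = 12L,
                                              class = 15L, phylum = 40L),
                            uniqueFunctionRate = 0.1,
                            annotationRates = c(known = 0.5,
                                                hypothetical = 0.3,
                                                unknown = 0.2),
                            annotationPurity = 1,
                            paralogRate = 0.1,
                            identityJitterSd = 0,
                            spuriousHitRate = 0,
                            withSequences = FALSE) {
  cfg <- list(seed = as.integer(seed), nPhyla = as.integer(nPhyla),
              classesPerPhylum = as.integer(classesPerPhylum),
              ordersPerClass = as.integer(ordersPerClass),
              familiesPerOrder = as.integer(familiesPerOrder),
              generaPerFamily = as.integer(generaPerFamily),
              speciesPerGenus = as.integer(speciesPerGenus),
              organismsPerSpecies = as.integer(organismsPerSpecies),
              corePoolSizes = corePoolSizes,
              uniqueFunctionRate = uniqueFunctionRate,
              annotationRates = annotationRates,
              annotationPurity = annotationPurity,
              paralogRate = paralogRate,
              identityJitterSd = identityJitterSd,
              spuriousHitRate = spuriousHitRate,
              withSequences = isTRUE(withSequences))
  counts <- unlist(cfg[c("nPhyla", "classesPerPhylum", "ordersPerClass",
                         "familiesPerOrder", "generaPerFamily",
                         "speciesPerGenus", "organismsPerSpecies")])
  if (any(counts < 1L)) stop("all taxonomy counts must be >= 1")
  if (!all(TAXONOMY_RANKS %in% names(corePoolSizes)))
    stop("corePoolSizes must be named by all taxonomy ranks")
  if (any(corePoolSizes < 1L)) stop("core pool sizes must be >= 1")
  rates <- c(uniqueFunctionRate, annotationRates, paralogRate,
             spuriousHitRate, annotationPurity)
  if (any(rates < 0) || any(c(uniqueFunctionRate, annotationRates,
                              paralogRate, annotationPurity) > 1))
    stop("rates must lie in [0, 1]")
  if (abs(sum(annotationRates) - 1) > 1e-8)
    stop("annotationRates must sum to 1")
  if (uniqueFunctionRate >= 1) stop("uniqueFunctionRate must be < 1")
  if (identityJitterSd < 0) stop("identityJitterSd must be >= 0")
  cfg
}

# the subtracted curve of the middle HSSP branch
.hsspCurve <- function(L) 480 * L^(-0.32 * (1 + exp(-L / 1000)))

.fabricateHits <- function(p1, p2, targetLo, targetHi, jitterSd) {
  n <- length(p1)
  L <- sample(50:400, n, replace = TRUE)
  target <- stats::runif(n, targetLo, targetHi)
  Id <- target + .hsspCurve(L) + stats::rnorm(n, 0, jitterSd)
  Id <- pmin(100, pmax(0, Id))
  flip <- stats::runif(n) < 0.5
  data.table(query = ifelse(flip, p2, p1),
             subject = ifelse(flip, p1, p2),
             identity = round(Id, 3), length = as.integer(L))
}

#' Generate a fully self-contained synthetic dataset
#'
#' Fabricates a balanced taxonomy, organisms built from nested function
#' pools plus organism-unique functions, in-paralogs, an alignment-hit
#' table engineered so that (absent noise) same-function pairs have
#' HSSP distance >= 10 and different-function pairs < 10, and an
#' annotation table following the known/hypothetical/unknown trigger
#' conventions. All outputs are deterministic for a fixed seed.
#'
#' @param config from [syntheticConfig()].
#' @param outDir optional directory; when given, writes
#'   `alignments.tsv`, `annotations.tsv`, `taxonomy.tsv`,
#'   `manifest.tsv` (and `proteins.faa` with sequences enabled).
#' @return list with elements `proteins` (data.table: protein_id,
#'   organism_id, function_id), `hits`, `annotations`, `taxonomy`,
#'   `groundTruth` (planted memberships, categories, repertoires,
#'   per-level similarities and designed separating cut-offs) and
#'   `files` (paths, when `outDir` was given).
#' @export
generateSyntheticDataset <- function(config = syntheticConfig(),
                                     outDir = NULL) {
  .withSeed(config$seed, .generateSynthetic(config, outDir))
}

.generateSynthetic <- function(config, outDir) {
  pool <- config$corePoolSizes
  # enumerate the balanced taxonomy
  orgs <- list()
  for (p in seq_len(config$nPhyla))
    for (cl in seq_len(config$classesPerPhylum))
      for (o in seq_len(config$ordersPerClass))
        for (f in seq_len(config$familiesPerOrder))
          for (g in seq_len(config$generaPerFamily))
            for (s in seq_len(config$speciesPerGenus))
              for (i in seq_len(config$organismsPerSpecies)) {
                nodes <- c(
                  phylum = sprintf("ph%d", p),
                  class = sprintf("ph%dc%d", p, cl),
                  order = sprintf("ph%dc%do%d", p, cl, o),
                  family = sprintf("ph%dc%do%df%d", p, cl, o, f),
                  genus = sprintf("ph%dc%do%df%dg%d", p, cl, o, f, g),
                  species = sprintf("ph%dc%do%df%dg%ds%d",
                                    p, cl, o, f, g, s))
                orgs[[length(orgs) + 1L]] <- c(
                  nodes, organism_id = sprintf("%sx%d", nodes[["species"]], i))
              }
  orgdf <- as.data.frame(do.call(rbind, orgs), stringsAsFactors = FALSE)
  taxonomy <- orgdf[, c("organism_id", TAXONOMY_RANKS)]

  # function pools per taxon node
  nodePool <- list()
  for (lev in TAXONOMY_RANKS) {
    for (node in unique(orgdf[[lev]])) {
      nodePool[[node]] <- sprintf("Fn_%s_%d", node, seq_len(pool[[lev]]))
    }
  }
  coreTotal <- sum(pool[TAXONOMY_RANKS])
  r <- config$uniqueFunctionRate
  nUnique <- round(r / (1 - r) * coreTotal)

  repertoires <- list()
  for (k in seq_len(nrow(orgdf))) {
    org <- orgdf$organism_id[k]
    core <- unlist(nodePool[unlist(orgdf[k, TAXONOMY_RANKS])],
                   use.names = FALSE)
    uniq <- if (nUnique > 0) sprintf("Fu_%s_%d", org, seq_len(nUnique))
            else character(0)
    repertoires[[org]] <- c(core, uniq)
  }

  # proteins: one per organism x function, plus in-paralogs
  orgcol <- rep(names(repertoires), lengths(repertoires))
  funcol <- unlist(repertoires, use.names = FALSE)
  copies <- 1L + stats::rbinom(length(funcol), 1L, config$paralogRate)
  proteins <- data.table(
    organism_id = rep(orgcol, copies),
    function_id = rep(funcol, copies))
  proteins[, protein_id := sprintf("P_%s_%05d", organism_id,
                                   seq_len(.N)), by = "organism_id"]
  data.table::setcolorder(proteins,
                          c("protein_id", "organism_id", "function_id"))

  # per-function category and annotation text
  allFun <- unique(funcol)
  cat_ <- sample(c("known", "hypothetical", "unknown"), length(allFun),
                 replace = TRUE, prob = unname(
                   config$annotationRates[c("known", "hypothetical",
                                            "unknown")]))
  names(cat_) <- allFun
  vocab <- c("DNA polymerase III subunit", "ABC transporter permease",
             "30S ribosomal protein", "aspartate aminotransferase",
             "GTP-binding elongation factor", "cell division protein",
             "sugar kinase", "two-component response regulator",
             "ATP-dependent RNA helicase", "signal peptidase")
  hyText <- c("hypothetical protein", "putative membrane protein",
              "protein")
  annOf <- character(length(allFun))
  names(annOf) <- allFun
  isKn <- cat_ == "known"
  annOf[isKn] <- paste(sample(vocab, sum(isKn), replace = TRUE),
                       gsub("[^A-Za-z0-9]", "", allFun[isKn]))
  isHy <- cat_ == "hypothetical"
  annOf[isHy] <- sample(hyText, sum(isHy), replace = TRUE)

  annotated <- proteins$function_id %in% allFun[isKn | isHy]
  annotations <- stats::setNames(
    annOf[proteins$function_id[annotated]],
    proteins$protein_id[annotated])
  if (config$annotationPurity < 1) {
    knP <- which(cat_[proteins$function_id[annotated]] == "known")
    impure <- knP[stats::runif(length(knP)) > config$annotationPurity]
    annotations[impure] <- paste(annotations[impure], "isoform")
  }

  # true same-function hits
  byFun <- split(proteins$protein_id, proteins$function_id)
  pairsOf <- function(ids) {
    if (length(ids) < 2L) return(NULL)
    cb <- utils::combn(sort(ids), 2L)
    list(p1 = cb[1L, ], p2 = cb[2L, ])
  }
  pp <- lapply(byFun, pairsOf)
  pp <- pp[!vapply(pp, is.null, logical(1))]
  p1 <- unlist(lapply(pp, `[[`, "p1"), use.names = FALSE)
  p2 <- unlist(lapply(pp, `[[`, "p2"), use.names = FALSE)
  hits <- .fabricateHits(p1, p2, 15, 60, config$identityJitterSd)
  # all-vs-all aligners report a self-hit per protein; these carry the
  # protein universe into the alignment-only pipeline entry point
  selfHits <- data.table(query = proteins$protein_id,
                         subject = proteins$protein_id,
                         identity = 100,
                         length = as.integer(
                           sample(50:400, nrow(proteins), replace = TRUE)))
  hits <- rbind(selfHits, hits)

  # spurious different-function hits, engineered below threshold
  nSp <- round(config$spuriousHitRate * nrow(hits))
  if (nSp > 0) {
    a <- sample(proteins$protein_id, 2L * nSp, replace = TRUE)
    b <- sample(proteins$protein_id, 2L * nSp, replace = TRUE)
    fa <- proteins$function_id[match(a, proteins$protein_id)]
    fb <- proteins$function_id[match(b, proteins$protein_id)]
    ok <- which(a != b & fa != fb)[seq_len(min(nSp, sum(a != b & fa != fb)))]
    if (length(ok))
      hits <- rbind(hits, .fabricateHits(a[ok], b[ok], -30, -5,
                                         config$identityJitterSd))
  }

  groundTruth <- list(
    functionOf = stats::setNames(proteins$function_id,
                                 proteins$protein_id),
    categories = cat_,
    repertoires = repertoires,
    taxonomy = taxonomy)
  # per-level similarity plateaus and designed separating cut-offs
  share <- numeric(length(TAXONOMY_RANKS))
  names(share) <- TAXONOMY_RANKS
  cum <- 0
  for (lev in rev(TAXONOMY_RANKS)) {   # phylum first
    cum <- cum + pool[[lev]]
    share[lev] <- cum
  }
  Rsize <- coreTotal + nUnique
  groundTruth$levelSimilarity <- share / Rsize
  parentShare <- stats::setNames(
    c(share[TAXONOMY_RANKS][-1], 0), TAXONOMY_RANKS)
  groundTruth$designedCutoffs <-
    (share + parentShare) / (2 * Rsize)

  out <- list(proteins = proteins, hits = hits,
              annotations = annotations, taxonomy = taxonomy,
              groundTruth = groundTruth, files = NULL)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    files <- c(alignments = file.path(outDir, "alignments.tsv"),
               annotations = file.path(outDir, "annotations.tsv"),
               taxonomy = file.path(outDir, "taxonomy.tsv"),
               manifest = file.path(outDir, "manifest.tsv"))
    fwrite(hits, files[["alignments"]], sep = "\t", col.names = FALSE)
    fwrite(data.table(protein_id = names(annotations),
                      annotation = unname(annotations)),
           files[["annotations"]], sep = "\t")
    fwrite(as.data.table(taxonomy), files[["taxonomy"]], sep = "\t")
    fwrite(proteins[, c("protein_id", "organism_id")],
           files[["manifest"]], sep = "\t")
    if (config$withSequences) {
      aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      seqs <- vapply(seq_len(nrow(proteins)), function(i)
        paste(sample(aa, sample(80:300, 1), replace = TRUE),
              collapse = ""), character(1))
      files <- c(files, fasta = file.path(outDir, "proteins.faa"))
      writeProteinFasta(
        data.frame(protein_id = proteins$protein_id, sequence = seqs),
        files[["fasta"]])
    }
    out$files <- files
  }
  out
}

#' Generate a similarity network with planted blocks
#'
#' Produces a complete similarity matrix in which organisms of the
#' same planted block are highly similar and cross-block pairs are
#' weakly similar, with optional Gaussian jitter -- the standard
#' planted-partition benchmark for module detection.
#'
#' @param sizes integer vector of block sizes.
#' @param intraMean,interMean mean similarity within / between blocks.
#' @param jitterSd Gaussian jitter SD on off-diagonal entries.
#' @param seed integer seed.
#' @return list with `network` (a [SimilarityNetwork-class]) and
#'   `partition` (named character vector, the planted blocks).
#' @export
generateBlockNetwork <- function(sizes = c(10L, 10L), intraMean = 0.9,
                                 interMean = 0.05, jitterSd = 0.02,
                                 seed = 1L) {
  stopifnot(all(sizes >= 1L), intraMean >= 0, intraMean <= 1,
            interMean >= 0, interMean <= 1, jitterSd >= 0)
  .withSeed(as.integer(seed), {
    n <- sum(sizes)
    orgs <- sprintf("org%03d", seq_len(n))
    block <- rep(sprintf("B%d", seq_along(sizes)), sizes)
    names(block) <- orgs
    s <- ifelse(outer(block, block, "=="), intraMean, interMean)
    jit <- matrix(stats::rnorm(n * n, 0, jitterSd), n, n)
    jit[upper.tri(jit)] <- t(jit)[upper.tri(jit)]
    s <- s + jit
    s[s < 0] <- 0
    s[s > 1] <- 1
    diag(s) <- 1
    dimnames(s) <- list(orgs, orgs)
    list(network = new("SimilarityNetwork", sim = s), partition = block)
  })
}
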