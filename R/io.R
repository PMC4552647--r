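#' @importFrom data.table fread fwrite data.table as.data.table setnames :=
NULL

#' Taxonomic ranks, lowest to highest
#'
#' The fixed lineage order used throughout: species, genus, family,
#' order, class, phylum.
#' @export
TAXONOMY_RANKS <- c("species", "genus", "family", "order", "class", "phylum")

#' Read a protein FASTA file
#'
#' Headers follow the convention that the first whitespace-delimited
#' token is the protein id. Organism ids are not parsed from headers:
#' they come either from a per-file assignment (`organism`) or from a
#' manifest table (protein id -> organism id).
#'
#' @param path FASTA file.
#' @param organism single organism id assigned to every record, or NULL.
#' @param manifest optional data.frame with columns `protein_id`,
#'   `organism_id` (see [readManifest()]); used when `organism` is NULL.
#' @return data.frame with columns `protein_id`, `organism_id`,
#'   `sequence`, in file order.
#' @export
readProteinFasta <- function(path, organism = NULL, manifest = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(protein_id = character(), organism_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  org <- if (!is.null(organism)) {
    rep(organism, length(ids))
  } else if (!is.null(manifest)) {
    m <- stats::setNames(manifest$organism_id, manifest$protein_id)
    miss <- setdiff(ids, names(m))
    if (length(miss))
      stop("protein id(s) absent from manifest: ",
           paste(utils::head(miss, 5), collapse = ", "))
    unname(m[ids])
  } else {
    rep(NA_character_, length(ids))
  }
  data.frame(protein_id = ids, organism_id = org,
             sequence = as.character(seqs), stringsAsFactors = FALSE)
}

#' Write protein records as FASTA
#'
#' @param records data.frame as returned by [readProteinFasta()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeProteinFasta <- function(records, path) {
  stopifnot(all(c("protein_id", "sequence") %in% names(records)))
  x <- Biostrings::AAStringSet(records$sequence)
  names(x) <- records$protein_id
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

.parseAlignmentChunk <- function(lines, first_line_no) {
  dt <- fread(text = lines, header = FALSE, sep = "\t",
              colClasses = "character", fill = TRUE)
  if (ncol(dt) < 4L)
    stop("alignment table needs >= 4 tab-separated columns (line ",
         first_line_no, ")")
  out <- data.table(query = dt[[1L]], subject = dt[[2L]],
                    identity = suppressWarnings(as.numeric(dt[[3L]])),
                    length = suppressWarnings(as.numeric(dt[[4L]])))
  bad <- which(is.na(out$identity) | is.na(out$length))
  if (length(bad))
    stop("non-numeric identity/length in alignment table at line ",
         first_line_no + bad[1L] - 1L)
  bad <- which(out$identity < 0 | out$identity > 100)
  if (length(bad))
    stop("percent identity outside [0, 100] at line ",
         first_line_no + bad[1L] - 1L)
  bad <- which(out$length < 1 | out$length != floor(out$length))
  if (length(bad))
    stop("alignment length must be a positive integer at line ",
         first_line_no + bad[1L] - 1L)
  out$length <- as.integer(out$length)
  out
}

#' Read a tabular all-vs-all alignment file
#'
#' Tab-separated, no header; columns 1-4 are query id, subject id,
#' percent identity in [0, 100] and alignment length (residues). The
#' common 12-column tabular alignment dialect is accepted; columns
#' beyond the fourth are ignored. Self-hits are passed through and
#' filtered downstream (see [consolidateBestHits()]).
#'
#' @param path alignment file.
#' @return data.table with columns `query`, `subject`, `identity`,
#'   `length`, in file order.
#' @seealso [streamAlignmentTable()] for bounded-memory processing.
#' @export
readAlignmentTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.table(query = character(), subject = character(),
                      identity = numeric(), length = integer()))
  .parseAlignmentChunk(lines, 1L)
}

#' Stream an alignment file in bounded memory
#'
#' Reads the file in chunks of `chunkSize` lines and calls `callback`
#' on each parsed chunk (a data.table as in [readAlignmentTable()]).
#' Only one chunk is held in memory at a time, so arbitrarily large
#' files can be consolidated.
#'
#' @param path alignment file.
#' @param callback function(chunk) invoked per chunk.
#' @param chunkSize lines per chunk.
#' @return invisibly, the number of data lines processed.
#' @export
streamAlignmentTable <- function(path, callback, chunkSize = 100000L) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, open = "r")
  on.exit(close(con), add = TRUE)
  line_no <- 1L
  total <- 0L
  repeat {
    lines <- readLines(con, n = chunkSize)
    if (!length(lines)) break
    keep <- nzchar(lines)
    if (any(keep)) callback(.parseAlignmentChunk(lines[keep], line_no))
    total <- total + sum(keep)
    line_no <- line_no + length(lines)
  }
  invisible(total)
}

#' Read a reference taxonomy table
#'
#' TSV with header columns `organism_id`, `species`, `genus`, `family`,
#' `order`, `class`, `phylum` (lineage low to high). Empty fields and
#' the literal `NA` denote a missing rank.
#'
#' @param path taxonomy TSV.
#' @return data.frame with the seven columns above, one row per organism.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = c("", "NA"))
  need <- c("organism_id", TAXONOMY_RANKS)
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("taxonomy table missing column(s): ", paste(miss, collapse = ", "))
  dup <- dt$organism_id[duplicated(dt$organism_id)]
  if (length(dup))
    stop("duplicate organism id(s) in taxonomy: ",
         paste(unique(dup), collapse = ", "))
  as.data.frame(dt[, need, with = FALSE])
}

#' Check that a taxonomy covers a set of organisms
#'
#' @param taxonomy data.frame as from [readTaxonomy()].
#' @param orgs character vector of organism ids that must be present.
#' @return invisibly TRUE; errors listing offenders otherwise.
#' @export
checkTaxonomyCovers <- function(taxonomy, orgs) {
  miss <- setdiff(orgs, taxonomy$organism_id)
  if (length(miss))
    stop("organism(s) absent from taxonomy: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}

#' Read a protein annotation table
#'
#' TSV with header columns `protein_id`, `annotation`. A protein absent
#' from the table has no annotation at all; an empty string is treated
#' the same way.
#'
#' @param path annotation TSV.
#' @return named character vector protein id -> annotation string.
#' @export
readAnnotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = NULL)
  if (!all(c("protein_id", "annotation") %in% names(dt)))
    stop("annotation table needs columns protein_id, annotation")
  dup <- dt$protein_id[duplicated(dt$protein_id)]
  if (length(dup))
    stop("duplicate protein id(s) in annotations: ",
         paste(unique(dup), collapse = ", "))
  stats::setNames(dt$annotation, dt$protein_id)
}

#' Read a protein-to-organism manifest
#'
#' TSV with header columns `protein_id`, `organism_id`.
#'
#' @param path manifest TSV.
#' @return data.frame with columns `protein_id`, `organism_id`.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (!all(c("protein_id", "organism_id") %in% names(dt)))
    stop("manifest needs columns protein_id, organism_id")
  dup <- dt$protein_id[duplicated(dt$protein_id)]
  if (length(dup))
    stop("duplicate protein id(s) in manifest: ",
         paste(unique(dup), collapse = ", "))
  as.data.frame(dt[, c("protein_id", "organism_id"), with = FALSE])
}

#' Write a similarity network as an edge list
#'
#' One line per unordered organism pair: `org_a\torg_b\tsimilarity`,
#' similarity printed at 6 decimals, with a header line.
#'
#' @param network a [SimilarityNetwork-class].
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(is(network, "SimilarityNetwork"))
  s <- similarityMatrix(network)
  orgs <- rownames(s)
  idx <- which(lower.tri(s), arr.ind = TRUE)
  dt <- data.table(org_a = orgs[idx[, 2L]], org_b = orgs[idx[, 1L]],
                   similarity = sprintf("%.6f", s[idx]))
  fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an edge-list TSV back into a SimilarityNetwork
#'
#' @param path edge-list TSV written by [writeEdgeList()].
#' @return a [SimilarityNetwork-class]; pairs absent from the file get
#'   similarity 0.
#' @export
readEdgeList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = 1:2))
  if (!all(c("org_a", "org_b", "similarity") %in% names(dt)))
    stop("edge list needs columns org_a, org_b, similarity")
  orgs <- sort(unique(c(dt$org_a, dt$org_b)))
  s <- matrix(0, length(orgs), length(orgs), dimnames = list(orgs, orgs))
  s[cbind(dt$org_a, dt$org_b)] <- dt$similarity
  s[cbind(dt$org_b, dt$org_a)] <- dt$similarity
  diag(s) <- 1
  new("SimilarityNetwork", sim = s)
}

#' Write function groups to a TSV
#'
#' Columns `group_id`, `protein_id`, `category` (NA before annotation),
#' plus `scope` when set.
#'
#' @param groups a [FunctionGroups-class].
#' @param path output TSV.
#' @return invisibly, the path.
#' @export
writeGroups <- function(groups, path) {
  stopifnot(is(groups, "FunctionGroups"))
  m <- proteinGroups(groups)
  cat_ <- groupCategory(groups)
  sc <- groupScope(groups)
  dt <- data.table(group_id = unname(m), protein_id = names(m))
  dt$category <- cat_[dt$group_id]
  dt$scope <- sc[dt$group_id]
  data.table::setorder(dt, group_id, protein_id)
  fwrite(dt, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a groups TSV back into a FunctionGroups object
#'
#' @param path TSV written by [writeGroups()].
#' @return a [FunctionGroups-class].
#' @export
readGroups <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
              na.strings = c("NA"))
  if (!all(c("group_id", "protein_id") %in% names(dt)))
    stop("groups table needs columns group_id, protein_id")
  membership <- stats::setNames(dt$group_id, dt$protein_id)
  cat_ <- character(0)
  if ("category" %in% names(dt)) {
    per <- dt[!is.na(dt$category), ]
    if (nrow(per)) cat_ <- stats::setNames(per$category, per$group_id)
    cat_ <- cat_[!duplicated(names(cat_))]
  }
  sc <- character(0)
  if ("scope" %in% names(dt)) {
    per <- dt[!is.na(dt$scope), ]
    if (nrow(per)) sc <- stats::setNames(per$scope, per$group_id)
    sc <- sc[!duplicated(names(sc))]
  }
  new("FunctionGroups", membership = membership, category = cat_, scope = sc)
}

#' Write a tree (or layered hierarchy) in Newick format
#'
#' @param tree an [ape::phylo] object or a [LayeredHierarchy-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeNewick <- function(tree, path) {
  if (is(tree, "LayeredHierarchy")) tree <- hierarchyTree(tree)
  if (!inherits(tree, "phylo")) stop("tree must be a phylo object")
  ape::write.tree(tree, file = path)
  invisible(path)
}
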