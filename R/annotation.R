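#' Categorize proteins by annotation text
#'
#' Each protein gets exactly one category from its free-text annotation:
#' \itemize{
#'   \item `unknown`: no annotation at all (absent or empty string);
#'   \item `hypothetical`: the annotation contains "hypothetical" or
#'     "putative" (case-insensitive substring, configurable to
#'     whole-word matching), or equals (case-insensitive, trimmed)
#'     "protein" or "Uncharacterized protein conserved in bacteria";
#'   \item `known`: any other annotation.
#' }
#'
#' @param annotation character vector of annotation strings; `NA` means
#'   no annotation.
#' @param wholeWord if TRUE the trigger words must appear as whole
#'   words rather than substrings; default FALSE (substring).
#' @return character vector of categories (`known`, `hypothetical`,
#'   `unknown`).
#' @export
categorizeProtein <- function(annotation, wholeWord = FALSE) {
  ann <- as.character(annotation)
  trimmed <- trimws(ann)
  lowered <- tolower(trimmed)
  unknown <- is.na(ann) | trimmed == ""
  pat <- if (wholeWord) "\\b(hypothetical|putative)\\b"
         else "(hypothetical|putative)"
  trigger <- !unknown & (grepl(pat, lowered) |
    lowered == "protein" |
    lowered == tolower("Uncharacterized protein conserved in bacteria"))
  out <- rep("known", length(ann))
  out[trigger] <- "hypothetical"
  out[unknown] <- "unknown"
  out
}

#' Categorize function groups as Kn / Hy / Un
#'
#' A group is `Kn` if it contains at least one `known` member, else
#' `Hy` if it contains at least one `hypothetical` member, else `Un`
#' (all members unannotated).
#'
#' @param groups a [FunctionGroups-class].
#' @param proteinCategories named character vector protein id ->
#'   category (as from [categorizeProtein()] on a full annotation set),
#'   or an annotation vector named by protein id, in which case it is
#'   categorized first.
#' @return the input `groups` with the `category` slot filled.
#' @export
categorizeGroups <- function(groups, proteinCategories) {
  stopifnot(is(groups, "FunctionGroups"))
  m <- proteinGroups(groups)
  if (is.null(names(proteinCategories)))
    stop("proteinCategories must be named by protein id")
  if (!all(proteinCategories %in% c("known", "hypothetical", "unknown")))
    proteinCategories <- stats::setNames(
      categorizeProtein(proteinCategories), names(proteinCategories))
  miss <- setdiff(names(m), names(proteinCategories))
  if (length(miss))
    stop("protein(s) missing a category: ",
         paste(utils::head(miss, 5), collapse = ", "))
  pc <- proteinCategories[names(m)]
  dt <- data.table(group = unname(m), cat = unname(pc))
  agg <- dt[, list(
    category = if (any(cat == "known")) "Kn"
               else if (any(cat == "hypothetical")) "Hy"
               else "Un"), by = "group"]
  groups@category <- stats::setNames(agg$category, agg$group)
  methods::validObject(groups)
  groups
}

#' Tag function groups as shared or unique across organisms
#'
#' A group is `shared` if its member proteins come from two or more
#' organisms, `unique` if from exactly one.
#'
#' @param groups a [FunctionGroups-class].
#' @param proteinOrganism named character vector protein id ->
#'   organism id.
#' @return the input `groups` with the `scope` slot filled.
#' @export
tagScope <- function(groups, proteinOrganism) {
  stopifnot(is(groups, "FunctionGroups"))
  m <- proteinGroups(groups)
  miss <- setdiff(names(m), names(proteinOrganism))
  if (length(miss))
    stop("protein(s) not mapped to an organism: ",
         paste(utils::head(miss, 5), collapse = ", "))
  org <- proteinOrganism[names(m)]
  dt <- data.table(group = unname(m), org = unname(org))
  agg <- dt[, list(norg = length(unique(org))), by = "group"]
  groups@scope <- stats::setNames(
    ifelse(agg$norg >= 2L, "shared", "unique"), agg$group)
  methods::validObject(groups)
  groups
}

#' Normalise an annotation string for consistency comparison
#'
#' Lowercases, collapses whitespace and strips trailing EC-number
#' qualifiers, so that cosmetic variants of the same annotation compare
#' equal.
#'
#' @param x character vector of annotation strings.
#' @return normalised character vector.
#' @export
normalizeAnnotation <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  x <- gsub("\\s*\\(?\\bec[ :]?[0-9]+(\\.[0-9n-]+){1,3}\\)?\\s*$", "", x)
  trimws(x)
}

#' Annotation consistency of Kn groups
#'
#' For each Kn group, the fraction of its annotated members whose
#' normalised annotation equals the group's most common one (modal
#' fraction). High modal fractions indicate that the sequence-derived
#' groups collect proteins annotators also call functionally identical.
#'
#' @param groups a categorized [FunctionGroups-class].
#' @param annotations named character vector protein id -> annotation.
#' @return data.frame with columns `group_id`, `n_annotated`,
#'   `modal_fraction`, one row per Kn group with at least one annotated
#'   member.
#' @export
annotationConsistency <- function(groups, annotations) {
  stopifnot(is(groups, "FunctionGroups"))
  cat_ <- groupCategory(groups)
  if (all(is.na(cat_)))
    stop("groups must be categorized first (see categorizeGroups)")
  kn <- names(cat_)[!is.na(cat_) & cat_ == "Kn"]
  m <- proteinGroups(groups)
  keep <- names(m)[m %in% kn]
  ann <- annotations[keep]
  annotated <- !is.na(ann) & trimws(ann) != ""
  if (!any(annotated))
    return(data.frame(group_id = character(), n_annotated = integer(),
                      modal_fraction = numeric()))
  dt <- data.table(group = unname(m[keep][annotated]),
                   ann = normalizeAnnotation(ann[annotated]))
  agg <- dt[, list(n_annotated = .N,
                   modal_fraction = max(table(ann)) / .N), by = "group"]
  data.table::setorder(agg, group)
  data.frame(group_id = agg$group, n_annotated = agg$n_annotated,
             modal_fraction = agg$modal_fraction)
}
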