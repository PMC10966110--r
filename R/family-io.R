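#' Read protein clusters in the MMseqs2 createtsv dialect
#'
#' Each line holds `representative TAB member`; a cluster is the set of
#' members sharing one representative and is keyed by the representative id.
#' A representative normally lists itself as a member; a cluster lacking its
#' self-row is tolerated with a warning.
#'
#' @param file path to the two-column TSV.
#' @param source label stored in the run metadata, default `"mmseqs"`.
#' @param cValue optional alignment-coverage cutoff tag of this run.
#' @return A [FamilyTable-class] without species attached.
#' @seealso [readMCLClusters()], [attachSpecies()]
#' @export
readMMseqsClusters <- function(file, source = "mmseqs", cValue = NA_real_) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L))
    stop("line ", which(nf != 2L)[1L], " of '", file,
         "' has ", nf[nf != 2L][1L], " tab-separated fields (expected 2)")
  rep_ <- vapply(parts, `[`, "", 1L)
  mem <- vapply(parts, `[`, "", 2L)
  dup <- mem[duplicated(mem)]
  for (m in unique(dup)) {
    if (length(unique(rep_[mem == m])) > 1L)
      stop("protein '", m, "' is assigned to more than one representative")
  }
  keep <- !duplicated(mem)
  rep_ <- rep_[keep]; mem <- mem[keep]
  fams <- split(mem, factor(rep_, levels = unique(rep_)))
  noSelf <- names(fams)[!mapply(function(id, members) id %in% members,
                                names(fams), fams)]
  if (length(noSelf))
    warning("representative(s) without a self-row: ",
            paste(utils::head(noSelf, 5L), collapse = ", "))
  new("FamilyTable", families = lapply(fams, unname),
      proteinSpecies = setNames(character(0), character(0)),
      source = source, cValue = cValue)
}

#' Read protein clusters in the MCL output dialect
#'
#' One cluster per line, members tab-separated; clusters are keyed
#' `MCL<line number>`. Duplicate members within a line are deduplicated with
#' a warning; a member appearing on two lines is an error.
#'
#' @inheritParams readMMseqsClusters
#' @return A [FamilyTable-class] without species attached.
#' @export
readMCLClusters <- function(file, source = "mcl", cValue = NA_real_) {
  lines <- readLines(file)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  fams <- list()
  for (i in seq_along(lines)) {
    toks <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    toks <- toks[nzchar(toks)]
    if (anyDuplicated(toks)) {
      warning("duplicate member(s) within cluster on line ", i,
              " deduplicated")
      toks <- unique(toks)
    }
    fams[[paste0("MCL", i)]] <- toks
  }
  all <- unlist(fams, use.names = FALSE)
  if (anyDuplicated(all))
    stop("protein(s) appear in more than one cluster: ",
         paste(utils::head(unique(all[duplicated(all)]), 5L), collapse = ", "))
  new("FamilyTable", families = fams,
      proteinSpecies = setNames(character(0), character(0)),
      source = source, cValue = cValue)
}

#' Attach species to the proteins of a family table
#'
#' Resolves every member protein to a species either through an explicit
#' two-column map (protein TAB species) or through the `"species|protein"` id
#' prefix convention. The per-family species sets (taxonomic composition)
#' derive from this map.
#'
#' @param fams a [FamilyTable-class]
#' @param mapping path to a protein->species TSV, or a named character vector
#'   (names = protein ids, values = species). Ignored under the prefix
#'   convention.
#' @param convention `"map"` or `"prefix"`.
#' @return The [FamilyTable-class] with `proteinSpecies` filled.
#' @export
attachSpecies <- function(fams, mapping = NULL,
                          convention = c("map", "prefix")) {
  convention <- match.arg(convention)
  prots <- unlist(fams@families, use.names = FALSE)
  if (convention == "prefix") {
    sp <- sub("\\|.*$", "", prots)
    bad <- prots[!grepl("|", prots, fixed = TRUE) | !nzchar(sp)]
    if (length(bad))
      stop("protein id(s) without a 'species|' prefix: ",
           paste(utils::head(bad, 10L), collapse = ", "))
    map <- setNames(sp, prots)
  } else {
    if (is.null(mapping)) stop("'mapping' is required under the map convention")
    if (is.character(mapping) && is.null(names(mapping)) &&
        length(mapping) == 1L) {
      tab <- utils::read.delim(mapping, header = FALSE,
                               colClasses = "character")
      if (ncol(tab) != 2L)
        stop("species map '", mapping, "' must have exactly 2 columns")
      map <- setNames(tab[[2L]], tab[[1L]])
    } else {
      map <- mapping
    }
    missing <- setdiff(prots, names(map))
    if (length(missing))
      stop("no species mapping for protein(s): ",
           paste(utils::head(missing, 10L), collapse = ", "))
    map <- map[prots]
  }
  fams@proteinSpecies <- map
  validObject(fams)
  fams
}

#' @describeIn FamilyTable-class family ids
#' @param x a `FamilyTable`
#' @aliases familyIDs
#' @export
familyIDs <- function(x) names(x@families)

#' @describeIn FamilyTable-class number of families
#' @export
nFamilies <- function(x) length(x@families)

#' @describeIn FamilyTable-class member protein ids of one family
#' @param family a family id
#' @export
familyMembers <- function(x, family) x@families[[family]]

#' @describeIn FamilyTable-class list of per-family species sets (requires
#'   attached species)
#' @export
familySpecies <- function(x) {
  if (!length(x@proteinSpecies) &&
      length(unlist(x@families, use.names = FALSE)))
    stop("species not attached; call attachSpecies() first")
  lapply(x@families, function(p) unique(unname(x@proteinSpecies[p])))
}

setMethod("show", "FamilyTable", function(object) {
  cat("FamilyTable:", length(object@families), "families,",
      length(unlist(object@families, use.names = FALSE)), "proteins\n")
  cat("  source:", object@source, " c value:", object@cValue,
      " species attached:", length(object@proteinSpecies) > 0L, "\n")
})

#' Drop species-specific single-protein clusters
#'
#' Removes every family whose taxonomic composition is a single species and
#' which has fewer than two member proteins. Such a cluster can only be
#' assigned to that species' terminal phylostratum on its own lineage, so the
#' global rule implements the per-lineage requirement that terminal
#' phylostrata retain only clusters with at least two members. The filter is
#' idempotent and never removes a multi-species family.
#'
#' @param fams a [FamilyTable-class] with species attached.
#' @return The filtered [FamilyTable-class].
#' @export
dropTerminalSingletons <- function(fams) {
  sp <- familySpecies(fams)
  nprot <- lengths(fams@families)
  keep <- lengths(sp) > 1L | nprot >= 2L
  fams@families <- fams@families[keep]
  fams
}

#' Read a protein-term annotation table
#'
#' One row per protein: `protein TAB term1,term2,...`. Proteins absent from
#' the table carry no annotation.
#'
#' @param file path to the TSV.
#' @return Named list, protein id -> character vector of term ids.
#' @export
readAnnotations <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 1L | nf > 2L))
    stop("line ", which(nf < 1L | nf > 2L)[1L], " of '", file,
         "' is not 'protein<TAB>terms'")
  prot <- vapply(parts, `[`, "", 1L)
  terms <- lapply(parts, function(p)
    if (length(p) < 2L || !nzchar(p[2L])) character(0) else
      unique(strsplit(p[2L], ",", fixed = TRUE)[[1L]]))
  if (anyDuplicated(prot)) {
    terms <- tapply(terms, factor(prot, levels = unique(prot)),
                    function(l) unique(unlist(l)), simplify = FALSE)
    prot <- unique(prot)
    terms <- terms[prot]
  }
  setNames(lapply(terms, as.character), prot)
}

#' Transfer protein annotations to families
#'
#' Under `"any"` mode a family receives every term carried by at least one
#' member protein. Under `"fraction"` mode a term is transferred only when at
#' least 50% of the member proteins carry it (inclusive threshold; all member
#' proteins count in the denominator, annotated or not). Families with no
#' resulting terms are labeled with the reserved pseudo-term `"NA"`.
#'
#' @param fams a [FamilyTable-class]
#' @param annotations path to a protein-term TSV (see [readAnnotations()]) or
#'   a named list protein id -> terms.
#' @param mode `"any"` (default) or `"fraction"`.
#' @return An [AnnotationMap-class].
#' @export
transferAnnotations <- function(fams, annotations, mode = c("any", "fraction")) {
  mode <- match.arg(mode)
  ann <- if (is.character(annotations) && length(annotations) == 1L)
    readAnnotations(annotations) else annotations
  familyTerms <- lapply(fams@families, function(members) {
    lst <- ann[intersect(members, names(ann))]
    if (mode == "any") {
      out <- unique(unlist(lst, use.names = FALSE))
    } else {
      counts <- table(unlist(lst, use.names = FALSE))
      out <- names(counts)[counts >= length(members) / 2]
    }
    if (!length(out)) out <- "NA"
    as.character(out)
  })
  new("AnnotationMap", proteinTerms = ann, familyTerms = familyTerms,
      mode = mode)
}

setMethod("show", "AnnotationMap", function(object) {
  cat("AnnotationMap (mode '", object@mode, "'): ",
      length(object@proteinTerms), " annotated proteins, ",
      length(object@familyTerms), " families\n", sep = "")
})

#' Normalized family table export
#'
#' @param fams a [FamilyTable-class] with species attached.
#' @param ann optional [AnnotationMap-class] supplying family terms.
#' @param file optional output path (TSV).
#' @return data.frame with columns `family_id`, `n_proteins`, `n_species`,
#'   `species_list`, `terms`.
#' @export
familyTableExport <- function(fams, ann = NULL, file = NULL) {
  sp <- familySpecies(fams)
  df <- data.frame(
    family_id = familyIDs(fams),
    n_proteins = unname(lengths(fams@families)),
    n_species = unname(lengths(sp)),
    species_list = vapply(sp, paste, "", collapse = ","),
    terms = if (is.null(ann)) "" else
      vapply(familyIDs(fams), function(f)
        paste(ann@familyTerms[[f]], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
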