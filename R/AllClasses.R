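#' @import methods
NULL

#' Rooted species phylogeny with precomputed navigation tables
#'
#' Wraps an [ape::read.tree()] `phylo` object and caches the structures every
#' downstream computation needs: the parent of each node, the ordered children
#' of each node, the set of descendant leaves below each node and each node's
#' depth (number of edges from the root). Node identity is positional: nodes
#' carry the stable integer ids assigned at parse time (tips `1..n`, internal
#' nodes `n+1..n+m`, ape convention), and all cross-references between objects
#' of this package use these ids.
#'
#' Branch lengths, if present in the input, are accepted and ignored: all
#' analyses in this package work on topological levels (ordinal evolutionary
#' time), never on branch lengths.
#'
#' @slot tree the underlying `phylo` object.
#' @slot parent integer vector, `parent[v]` is the parent node id of `v`
#'   (`NA` for the root).
#' @slot children list, `children[[v]]` are the child node ids of `v` in
#'   parse order (empty for leaves).
#' @slot root integer, the root node id.
#' @slot labels character vector over all nodes: tip labels for leaves,
#'   internal labels where the Newick supplied them, `""` otherwise.
#' @slot isLeaf logical vector over all nodes.
#' @slot descLeaves list, `descLeaves[[v]]` are the leaf ids in the subtree
#'   rooted at `v` (a leaf's set contains itself).
#' @slot depth integer vector, edges from the root (root has depth 0).
#'
#' @seealso [readPhylogeny()], [focalLineage()], [mrcaNode()]
#' @export
setClass("Phylogeny",
  slots = c(
    tree = "ANY",
    parent = "integer",
    children = "list",
    root = "integer",
    labels = "character",
    isLeaf = "logical",
    descLeaves = "list",
    depth = "integer"
  )
)

setValidity("Phylogeny", function(object) {
  n <- length(object@parent)
  if (length(object@labels) != n || length(object@isLeaf) != n ||
      length(object@children) != n || length(object@descLeaves) != n ||
      length(object@depth) != n)
    return("internal tables must all have one entry per node")
  if (sum(is.na(object@parent)) != 1L)
    return("exactly one node (the root) may lack a parent")
  if (is.na(object@parent[object@root]) == FALSE)
    return("root slot must point at the parentless node")
  tips <- object@labels[object@isLeaf]
  if (any(!nzchar(tips)))
    return("leaf names must be non-empty")
  dup <- tips[duplicated(tips)]
  if (length(dup))
    return(paste0("duplicate leaf name(s): ", paste(unique(dup), collapse = ", ")))
  # reachability from root doubles as the acyclicity check
  if (length(object@descLeaves[[object@root]]) != sum(object@isLeaf))
    return("every leaf must be reachable from the root")
  TRUE
})

#' Root-to-tip lineage of a focal species
#'
#' The ordered node path from the tree root to one focal leaf. Position `i` on
#' the path is phylostratum `i` (1-based): `ps1` is the root internode, `psN`
#' the focal species' terminal internode. Phylostratum names default to the
#' internal node labels of the tree where present, else `"ps<i>"`, and can be
#' overridden with a name table.
#'
#' @slot focal character, the focal species (a leaf name of the tree).
#' @slot path integer vector of node ids, `path[1]` = root,
#'   `path[N]` = focal leaf.
#' @slot psNames character vector parallel to `path`.
#' @seealso [focalLineage()], [nodeToPs()]
#' @export
setClass("FocalLineage",
  slots = c(focal = "character", path = "integer", psNames = "character")
)

setValidity("FocalLineage", function(object) {
  if (length(object@focal) != 1L || !nzchar(object@focal))
    return("focal must be a single non-empty species name")
  if (length(object@path) < 1L) return("path must be non-empty")
  if (length(object@psNames) != length(object@path))
    return("psNames must parallel path")
  TRUE
})

#' Gene-family (protein cluster) membership table
#'
#' Families are sets of protein ids; once species are attached every protein
#' maps to a species name, and the per-family species set (the family's
#' taxonomic composition) is derived from that map. A protein belongs to
#' exactly one family within one clustering run. A run is optionally tagged
#' with its clustering source and the alignment-coverage cutoff (c value) that
#' produced it.
#'
#' @slot families named list; `families[[id]]` is the character vector of
#'   member protein ids.
#' @slot proteinSpecies named character; protein id -> species name. Empty
#'   until [attachSpecies()] has been applied.
#' @slot source character, free-text label of the clustering source
#'   (e.g. `"mmseqs"`, `"mcl"`, `"simulated"`).
#' @slot cValue numeric, the minimum alignment-coverage fraction of the run
#'   (in `[0, 0.8]` for the standard grid) or `NA` when untagged.
#' @seealso [readMMseqsClusters()], [readMCLClusters()], [attachSpecies()],
#'   [dropTerminalSingletons()]
#' @export
setClass("FamilyTable",
  slots = c(
    families = "list",
    proteinSpecies = "character",
    source = "character",
    cValue = "numeric"
  ),
  prototype = prototype(source = NA_character_, cValue = NA_real_)
)

setValidity("FamilyTable", function(object) {
  ids <- names(object@families)
  if (length(object@families) && (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))))
    return("family ids must be unique and non-empty")
  prots <- unlist(object@families, use.names = FALSE)
  if (anyDuplicated(prots))
    return(paste0("protein(s) assigned to more than one family: ",
                  paste(utils::head(unique(prots[duplicated(prots)]), 5L), collapse = ", ")))
  if (length(object@proteinSpecies)) {
    missing <- setdiff(prots, names(object@proteinSpecies))
    if (length(missing))
      return(paste0("protein(s) without a species: ",
                    paste(utils::head(missing, 5L), collapse = ", ")))
  }
  TRUE
})

#' Functional-term annotations of proteins and families
#'
#' Carries the raw protein-level term sets and the family-level sets obtained
#' by annotation transfer. Two transfer modes exist: `"any"` assigns every
#' term carried by any member to the whole family; `"fraction"` requires at
#' least 50% of the member proteins (inclusive: exactly half qualifies) to
#' carry the term. Families that end up with no terms receive the reserved
#' pseudo-term `"NA"` so they still take part in contingency totals and can
#' themselves be tested for enrichment.
#'
#' @slot proteinTerms named list; protein id -> character vector of term ids.
#' @slot familyTerms named list; family id -> character vector of term ids.
#' @slot mode character, `"any"` or `"fraction"`.
#' @seealso [transferAnnotations()]
#' @export
setClass("AnnotationMap",
  slots = c(proteinTerms = "list", familyTerms = "list", mode = "character")
)

setValidity("AnnotationMap", function(object) {
  if (!object@mode %in% c("any", "fraction"))
    return("mode must be 'any' or 'fraction'")
  TRUE
})

#' Gain/loss events of gene families on one focal lineage
#'
#' One row per family that appears on the lineage: the phylostratum of its
#' gain (the position of the family's last-common-ancestor node on the focal
#' path) and, when the focal species lacks the family, the phylostratum of its
#' loss. Structural constraints hold by construction: a gain precedes its loss
#' by at least one internode (`loss_ps >= gain_ps + 2`) and no loss can be
#' placed before the third phylostratum from the root. Families whose
#' reconstruction would put the loss immediately after the gain (possible only
#' at polytomies) are excluded from the lineage and recorded in the
#' `excluded` side-channel rather than silently dropped.
#'
#' @slot events data.frame with columns `family`, `gain_ps`, `gain_node`,
#'   `loss_ps` (`NA` when the family survives to the focal tip), `loss_node`.
#' @slot focal character, focal species name.
#' @slot nPs integer, number of phylostrata on the lineage.
#' @slot excluded data.frame with columns `family`, `reason`.
#' @seealso [lineageEvents()], [contentProfile()]
#' @export
setClass("EventTable",
  slots = c(
    events = "data.frame",
    focal = "character",
    nPs = "integer",
    excluded = "data.frame"
  )
)

setValidity("EventTable", function(object) {
  ev <- object@events
  need <- c("family", "gain_ps", "gain_node", "loss_ps", "loss_node")
  if (!all(need %in% names(ev)))
    return(paste0("events must have columns: ", paste(need, collapse = ", ")))
  if (anyDuplicated(ev$family))
    return("a family may appear at most once per focal lineage")
  if (nrow(ev)) {
    if (any(ev$gain_ps < 1L | ev$gain_ps > object@nPs))
      return("gain_ps out of lineage range")
    has <- !is.na(ev$loss_ps)
    if (any(ev$loss_ps[has] < 3L))
      return("loss_ps must be >= 3 (third phylostratum from the root)")
    if (any(ev$loss_ps[has] < ev$gain_ps[has] + 2L))
      return("a gain must precede its loss by at least one internode")
  }
  TRUE
})

#' Union of gain/loss events over all lineages of the tree
#'
#' The whole-tree view: each family has exactly one gain node (the Dollo
#' single origin) and a possibly empty set of loss branches, each branch
#' identified by its child node and strictly below the gain node. Leaf sets of
#' the member species are kept so ancestral content can be evaluated at any
#' node.
#'
#' @slot gainNode named integer; family id -> gain node id.
#' @slot lossBranches named list; family id -> integer vector of child node
#'   ids of the branches on which the family is lost.
#' @slot familyLeaves named list; family id -> integer vector of leaf ids of
#'   the member species.
#' @seealso [unionEvents()], [ancestralContent()]
#' @export
setClass("UnionEvents",
  slots = c(gainNode = "integer", lossBranches = "list", familyLeaves = "list")
)

setValidity("UnionEvents", function(object) {
  ids <- names(object@gainNode)
  if (!identical(ids, names(object@lossBranches)) ||
      !identical(ids, names(object@familyLeaves)))
    return("gainNode, lossBranches and familyLeaves must share family ids")
  TRUE
})
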