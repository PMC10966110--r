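#' Read a rooted species phylogeny from Newick
#'
#' Parses a single rooted Newick tree (polytomies allowed) and precomputes the
#' navigation tables used by the rest of the package. Branch lengths are
#' accepted and discarded; internal node labels, if present, are recorded and
#' serve as default phylostratum names.
#'
#' @param file path to a Newick file containing one tree, or `NULL` when
#'   `text` is given.
#' @param text Newick string, used instead of `file` when non-`NULL`.
#' @return A [Phylogeny-class] object.
#' @examples
#' phy <- readPhylogeny(text = "((A,B),C);")
#' leafNames(phy)
#' @export
readPhylogeny <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either 'file' or 'text'")
    tr <- tryCatch(ape::read.tree(file), error = function(e)
      stop("malformed Newick in '", file, "': ", conditionMessage(e)))
  } else {
    tr <- tryCatch(ape::read.tree(text = text), error = function(e)
      stop("malformed Newick: ", conditionMessage(e)))
  }
  if (is.null(tr) || inherits(tr, "multiPhylo"))
    stop("input must contain exactly one well-formed tree")
  as.Phylogeny(tr)
}

#' Build a Phylogeny from an ape phylo object
#'
#' @param tree a `phylo` object. Interpreted as rooted at its root node even
#'   when the basal node is a polytomy.
#' @return A [Phylogeny-class] object.
#' @export
as.Phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  ntip <- length(tree$tip.label)
  if (ntip < 1L) stop("tree has no leaves")
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate leaf name(s): ", paste(dup, collapse = ", "))
  nnode <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nnode)
  children <- rep(list(integer(0)), nnode)
  # edge rows are in parse order, so children lists keep Newick order
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1L]; v <- tree$edge[i, 2L]
    parent[v] <- p
    children[[p]] <- c(children[[p]], v)
  }
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("tree must have exactly one root")
  isLeaf <- seq_len(nnode) <= ntip
  labels <- character(nnode)
  labels[seq_len(ntip)] <- tree$tip.label
  if (!is.null(tree$node.label))
    labels[ntip + seq_along(tree$node.label)] <- tree$node.label
  labels[is.na(labels)] <- ""

  # postorder accumulation of descendant leaves and preorder depths
  ord <- .postorderNodes(root, children)
  descLeaves <- rep(list(integer(0)), nnode)
  for (v in ord) {
    descLeaves[[v]] <- if (isLeaf[v]) v else
      unlist(descLeaves[children[[v]]], use.names = FALSE)
  }
  depth <- integer(nnode)
  for (v in rev(ord)) if (!is.na(parent[v])) depth[v] <- depth[parent[v]] + 1L

  new("Phylogeny", tree = tree, parent = parent, children = children,
      root = root, labels = labels, isLeaf = isLeaf,
      descLeaves = descLeaves, depth = depth)
}

.postorderNodes <- function(root, children) {
  n <- length(children)
  out <- integer(n); top <- 0L
  stack <- integer(n); stack[1L] <- root; sp <- 1L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    top <- top + 1L; out[top] <- v
    kids <- children[[v]]
    if (length(kids)) {
      stack[sp + seq_along(kids)] <- kids
      sp <- sp + length(kids)
    }
  }
  rev(out[seq_len(top)])
}

#' @describeIn Phylogeny-class number of nodes (leaves + internal)
#' @param x,object a `Phylogeny`
#' @aliases nNodes
#' @export
nNodes <- function(x) length(x@parent)

#' @describeIn Phylogeny-class leaf names in ape tip order
#' @export
leafNames <- function(x) x@labels[x@isLeaf]

#' @describeIn Phylogeny-class the root node id
#' @export
rootNode <- function(x) x@root

#' @describeIn Phylogeny-class leaf node id for each species name
#' @param species character vector of leaf names
#' @export
leafId <- function(x, species) {
  id <- match(species, x@labels)
  bad <- species[is.na(id) | id > sum(x@isLeaf)]
  if (length(bad))
    stop("unknown species: ", paste(utils::head(bad, 10L), collapse = ", "))
  id
}

setMethod("show", "Phylogeny", function(object) {
  cat("Phylogeny with", sum(object@isLeaf), "leaves and",
      sum(!object@isLeaf), "internal nodes\n")
  cat("  root node:", object@root,
      " max depth:", max(object@depth), "\n")
  tips <- leafNames(object)
  cat("  leaves:", paste(utils::head(tips, 6L), collapse = ", "),
      if (length(tips) > 6L) "..." else "", "\n")
})

#' Write a Phylogeny back to Newick
#'
#' @param x a [Phylogeny-class]
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when writing to a file).
#' @export
writeNewick <- function(x, file = NULL) {
  s <- ape::write.tree(x@tree)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Most recent common ancestor of a species set
#'
#' Returns the unique deepest node that is ancestral to (or equal to) every
#' listed leaf; for a singleton set this is the leaf itself.
#'
#' @param phy a [Phylogeny-class]
#' @param species non-empty character vector of leaf names.
#' @return Integer node id.
#' @examples
#' phy <- readPhylogeny(text = "((A,B),C);")
#' mrcaNode(phy, c("A", "B"))
#' @export
mrcaNode <- function(phy, species) {
  if (!length(species)) stop("species set must be non-empty")
  ids <- leafId(phy, unique(species))
  .mrcaOfLeaves(phy, ids)
}

# ids are leaf node ids; climbs from the first leaf until all are covered
.mrcaOfLeaves <- function(phy, ids) {
  cur <- ids[1L]
  while (!all(ids %in% phy@descLeaves[[cur]])) cur <- phy@parent[cur]
  cur
}

#' Root-to-tip lineage and phylostratum indexing of a focal species
#'
#' @param phy a [Phylogeny-class]
#' @param focal a leaf name of `phy`.
#' @param psNames optional character vector of phylostratum names, one per
#'   path position. Defaults to the tree's internal node labels where present
#'   and `"ps<i>"` elsewhere.
#' @return A [FocalLineage-class]; its path length N is the number of
#'   phylostrata of this lineage.
#' @examples
#' phy <- readPhylogeny(text = "((A,B),C);")
#' lin <- focalLineage(phy, "A")
#' nPhylostrata(lin)
#' @export
focalLineage <- function(phy, focal, psNames = NULL) {
  tip <- leafId(phy, focal)
  path <- tip
  while (!is.na(phy@parent[path[1L]])) path <- c(phy@parent[path[1L]], path)
  if (is.null(psNames)) {
    psNames <- phy@labels[path]
    psNames[!nzchar(psNames)] <- paste0("ps", seq_along(path))[!nzchar(psNames)]
  }
  if (length(psNames) != length(path))
    stop("psNames must have one entry per phylostratum (", length(path), ")")
  new("FocalLineage", focal = focal, path = path, psNames = psNames)
}

#' @describeIn FocalLineage-class number of phylostrata (path length)
#' @param x a `FocalLineage`
#' @aliases nPhylostrata
#' @export
nPhylostrata <- function(x) length(x@path)

setMethod("show", "FocalLineage", function(object) {
  cat("FocalLineage of '", object@focal, "': ",
      length(object@path), " phylostrata\n", sep = "")
  cat("  path nodes:", paste(object@path, collapse = " -> "), "\n")
})

#' Map a tree node to its phylostratum on a focal lineage
#'
#' @param lineage a [FocalLineage-class]
#' @param node integer node id of the same tree.
#' @param nNodes optional total node count of the tree, used to validate
#'   `node`; foreign ids are rejected when supplied.
#' @return The 1-based phylostratum index, or `NA` when the node lies off the
#'   focal path.
#' @export
nodeToPs <- function(lineage, node, nNodes = NULL) {
  if (length(node) != 1L || is.na(node) || node < 1L)
    stop("'node' must be a single positive node id")
  if (!is.null(nNodes) && node > nNodes)
    stop("node id ", node, " does not belong to this tree")
  match(as.integer(node), lineage@path)
}

#' Per-phylostratum lineage report
#'
#' One row per phylostratum of a focal lineage: node id, phylostratum name and
#' the number of extant species descending from the node.
#'
#' @param phy a [Phylogeny-class]
#' @param lineage a [FocalLineage-class] of `phy`.
#' @return data.frame with columns `focal_species`, `ps_index`, `node_id`,
#'   `ps_name`, `n_descendant_species`.
#' @export
lineageReport <- function(phy, lineage) {
  data.frame(
    focal_species = lineage@focal,
    ps_index = seq_along(lineage@path),
    node_id = lineage@path,
    ps_name = lineage@psNames,
    n_descendant_species = vapply(phy@descLeaves[lineage@path], length, 1L),
    stringsAsFactors = FALSE
  )
}
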