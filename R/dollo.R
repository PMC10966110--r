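#' Dollo gain phylostratum of one family on a focal lineage
#'
#' Under Dollo parsimony a family originates exactly once, at the last common
#' ancestor of the species that carry it; that node is the unique minimum-loss
#' single-origin solution. The gain phylostratum is the position of this node
#' on the focal root-to-tip path; a family whose origin lies off the path
#' never appears on this lineage.
#'
#' @param phy a [Phylogeny-class]
#' @param lineage a [FocalLineage-class] of `phy`.
#' @param species non-empty character vector of the family's species.
#' @return Integer gain phylostratum, or `NA` when the gain node is off the
#'   focal path. The gain node id is attached as attribute `"node"`.
#' @examples
#' phy <- readPhylogeny(text = "(((A,B),(C,D)),(E,F));")
#' lin <- focalLineage(phy, "A")
#' inferGain(phy, lin, c("A", "B"))   # 3
#' @export
inferGain <- function(phy, lineage, species) {
  g <- mrcaNode(phy, species)
  ps <- match(g, lineage@path)
  structure(ps, node = g)
}

#' Dollo loss phylostratum of one family on a focal lineage
#'
#' A family is present at a path node v iff v descends from (or equals) the
#' gain node and the subtree of v still contains at least one member species.
#' The loss phylostratum is the first path position at which the family is
#' absent while present at the parent position; no loss is reported when the
#' focal species itself carries the family.
#'
#' @inheritParams inferGain
#' @param gainPs the gain phylostratum returned by [inferGain()] (not `NA`).
#' @return Integer loss phylostratum, or `NA` when the family survives to the
#'   focal tip. The node id at which the family disappears is attached as
#'   attribute `"node"`.
#' @export
inferLoss <- function(phy, lineage, species, gainPs) {
  if (is.na(gainPs)) stop("gainPs must not be NA")
  g2 <- mrcaNode(phy, species)
  if (!identical(lineage@path[gainPs], g2))
    stop("internal error: gainPs inconsistent with the species set")
  ids <- leafId(phy, unique(species))
  n <- length(lineage@path)
  if (gainPs == n) return(structure(NA_integer_, node = NA_integer_))
  for (i in seq.int(gainPs + 1L, n)) {
    if (!any(ids %in% phy@descLeaves[[lineage@path[i]]]))
      return(structure(i, node = lineage@path[i]))
  }
  structure(NA_integer_, node = NA_integer_)
}

#' Gain/loss event table of a family set on one focal lineage
#'
#' Applies [inferGain()] and [inferLoss()] to every family of the table and
#' keeps the rows whose gain node lies on the focal path. A family whose
#' reconstruction places the loss in the phylostratum immediately after the
#' gain (possible only when the gain node is a polytomy) does not belong to
#' the focal lineage at all — it is specific to a side branch — and is
#' excluded, with the exclusion recorded in the side-channel rather than
#' silently dropped. Consequently every reported loss lies at least two
#' phylostrata after its gain and never before the third phylostratum from
#' the root.
#'
#' @param fams a [FamilyTable-class] with species attached (and the terminal
#'   singleton filter already applied, where desired).
#' @param phy a [Phylogeny-class]
#' @param focal focal species name, or a ready [FocalLineage-class].
#' @return An [EventTable-class].
#' @export
lineageEvents <- function(fams, phy, focal) {
  lineage <- if (is(focal, "FocalLineage")) focal else focalLineage(phy, focal)
  spsets <- familySpecies(fams)
  ids <- familyIDs(fams)
  n <- length(lineage@path)
  fam <- character(0); gps <- integer(0); gnode <- integer(0)
  lps <- integer(0); lnode <- integer(0)
  exFam <- character(0); exReason <- character(0)
  for (j in seq_along(ids)) {
    g <- inferGain(phy, lineage, spsets[[j]])
    if (is.na(g)) next
    l <- inferLoss(phy, lineage, spsets[[j]], g)
    if (!is.na(l) && l == g + 1L) {
      exFam <- c(exFam, ids[j])
      exReason <- c(exReason, "loss_immediately_after_gain")
      next
    }
    fam <- c(fam, ids[j]); gps <- c(gps, as.integer(g))
    gnode <- c(gnode, attr(g, "node"))
    lps <- c(lps, as.integer(l)); lnode <- c(lnode, attr(l, "node"))
  }
  new("EventTable",
      events = data.frame(family = fam, gain_ps = gps, gain_node = gnode,
                          loss_ps = lps, loss_node = lnode,
                          stringsAsFactors = FALSE),
      focal = lineage@focal, nPs = as.integer(n),
      excluded = data.frame(family = exFam, reason = exReason,
                            stringsAsFactors = FALSE))
}

#' @describeIn EventTable-class the events as a data.frame
#' @param x an `EventTable`
#' @aliases events
#' @export
events <- function(x) x@events

#' @describeIn EventTable-class families excluded by the
#'   immediate-loss rule
#' @export
excludedFamilies <- function(x) x@excluded

setMethod("show", "EventTable", function(object) {
  cat("EventTable for '", object@focal, "' (", object@nPs,
      " phylostrata): ", nrow(object@events), " families, ",
      sum(!is.na(object@events$loss_ps)), " with a loss event, ",
      nrow(object@excluded), " excluded\n", sep = "")
})

#' Union of gain and loss events over all lineages of the tree
#'
#' The whole-tree gain/loss profile: each family's single Dollo origin (the
#' LCA of its species set, identical from whichever lineage it is seen) plus
#' the branches, identified by their child nodes, on which the family is lost
#' — the edges whose parent subtree still contains a member species while the
#' child subtree does not. Losses reported by different lineages sharing a
#' branch coincide, so the union is computed once per family directly on the
#' tree.
#'
#' @param fams a [FamilyTable-class] with species attached.
#' @param phy a [Phylogeny-class]
#' @return A [UnionEvents-class].
#' @export
unionEvents <- function(fams, phy) {
  spsets <- familySpecies(fams)
  ids <- familyIDs(fams)
  gain <- integer(length(ids))
  lossBr <- vector("list", length(ids))
  leaves <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    lv <- leafId(phy, spsets[[j]])
    g <- .mrcaOfLeaves(phy, lv)
    gain[j] <- g
    leaves[[j]] <- lv
    # walk the subtree of g; a loss branch is present-parent -> absent-child
    loss <- integer(0)
    stack <- g
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (w in phy@children[[v]]) {
        if (any(lv %in% phy@descLeaves[[w]])) stack <- c(stack, w)
        else loss <- c(loss, w)
      }
    }
    lossBr[[j]] <- sort(loss)
  }
  new("UnionEvents",
      gainNode = setNames(gain, ids),
      lossBranches = setNames(lossBr, ids),
      familyLeaves = setNames(leaves, ids))
}

setMethod("show", "UnionEvents", function(object) {
  cat("UnionEvents:", length(object@gainNode), "families,",
      sum(lengths(object@lossBranches)), "loss branches\n")
})

#' Export tables for events
#'
#' @param x an [EventTable-class] or [UnionEvents-class]
#' @param lineage for `EventTable`, the matching [FocalLineage-class]
#'   (optional, adds ps names).
#' @param file optional output TSV path.
#' @return data.frame in the documented column layout.
#' @export
eventTableExport <- function(x, lineage = NULL, file = NULL) {
  ev <- x@events
  df <- data.frame(
    focal_species = rep(x@focal, nrow(ev)),
    family_id = ev$family,
    gain_ps = ev$gain_ps,
    gain_node_id = ev$gain_node,
    loss_ps = ifelse(is.na(ev$loss_ps), "", ev$loss_ps),
    loss_node_id = ifelse(is.na(ev$loss_node), "", ev$loss_node),
    stringsAsFactors = FALSE
  )
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

#' @rdname eventTableExport
#' @export
unionEventsExport <- function(x, file = NULL) {
  df <- data.frame(
    family_id = names(x@gainNode),
    gain_node_id = unname(x@gainNode),
    loss_branch_child_ids = vapply(x@lossBranches, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
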