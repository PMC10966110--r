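#' Simulate a rooted species tree
#'
#' Either a random rooted bifurcating topology (via [ape::rtree()], branch
#' lengths dropped) or the deterministic caterpillar (fully pectinate) shape.
#' Leaves are named `S1..Sn`. With a seed the output is fully reproducible.
#'
#' @param nLeaves number of leaves, at least 2.
#' @param topology `"random"` or `"caterpillar"`.
#' @param seed optional integer seed for the random topology.
#' @return A [Phylogeny-class].
#' @examples
#' writeNewick(simulateTree(4, "caterpillar"))
#' @export
simulateTree <- function(nLeaves, topology = c("random", "caterpillar"),
                         seed = NULL) {
  topology <- match.arg(topology)
  if (nLeaves < 2L) stop("nLeaves must be at least 2")
  tips <- paste0("S", seq_len(nLeaves))
  if (topology == "caterpillar") {
    nwk <- paste0("(", tips[1L], ",", tips[2L], ")")
    for (i in seq_len(nLeaves - 2L) + 2L) nwk <- paste0("(", nwk, ",", tips[i], ")")
    return(readPhylogeny(text = paste0(nwk, ";")))
  }
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(nLeaves, tip.label = tips)
  tr$edge.length <- NULL
  as.Phylogeny(tr)
}

#' Simulate Dollo-compatible gene-family evolution on a tree
#'
#' Each family is gained at exactly one node (drawn uniformly over all nodes,
#' or by the supplied per-node weights) and lost independently with
#' probability `lossProb` on every branch strictly below the gain node;
#' subtrees pruned by a loss are not evaluated further, so there is no regain
#' — the generative process matches the Dollo inference model by
#' construction. Surviving species are the leaves below the gain node avoiding
#' every loss branch; a family losing all its species is discarded and drawn
#' again, so the requested family count is exact (the regeneration count is
#' recorded). Every surviving species contributes at least one protein, with
#' the paralog count drawn from a geometric distribution with the stated mean;
#' protein ids follow the `species|family|index` convention.
#'
#' @param phy a [Phylogeny-class]
#' @param nFamilies number of families to generate.
#' @param lossProb per-branch loss probability `q` in `[0, 1)`.
#' @param gainWeights optional non-negative weight per node id (length
#'   `nNodes(phy)`); default uniform over all nodes.
#' @param paralogMean mean of the per-species paralog count, at least 1.
#' @param seed optional integer seed.
#' @return List with elements `familyTable` (a [FamilyTable-class] with
#'   species attached, source `"simulated"`) and `groundTruth` (list with
#'   per-family `gainNode`, `lossBranches`, `survivors`, plus the total
#'   `regenerated` count).
#' @export
simulateFamilies <- function(phy, nFamilies, lossProb = 0.1,
                             gainWeights = NULL, paralogMean = 1.5,
                             seed = NULL) {
  if (lossProb < 0 || lossProb >= 1) stop("lossProb must lie in [0, 1)")
  if (paralogMean < 1) stop("paralogMean must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  nn <- nNodes(phy)
  if (is.null(gainWeights)) gainWeights <- rep(1, nn)
  if (length(gainWeights) != nn || any(gainWeights < 0) ||
      sum(gainWeights) == 0)
    stop("gainWeights must be non-negative with one entry per node")
  families <- vector("list", nFamilies)
  proteinSpecies <- list()
  gt <- list(gainNode = integer(nFamilies),
             lossBranches = vector("list", nFamilies),
             survivors = vector("list", nFamilies),
             regenerated = 0L)
  famIds <- sprintf("fam%04d", seq_len(nFamilies))
  for (j in seq_len(nFamilies)) {
    repeat {
      g <- sample.int(nn, 1L, prob = gainWeights)
      loss <- integer(0)
      surv <- integer(0)
      stack <- g
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (phy@isLeaf[v]) { surv <- c(surv, v); next }
        for (w in phy@children[[v]]) {
          if (stats::runif(1) < lossProb) loss <- c(loss, w)
          else stack <- c(stack, w)
        }
      }
      if (length(surv)) break
      gt$regenerated <- gt$regenerated + 1L
    }
    gt$gainNode[j] <- g
    gt$lossBranches[[j]] <- sort(loss)
    gt$survivors[[j]] <- sort(surv)
    sp <- phy@labels[sort(surv)]
    nPar <- 1L + stats::rgeom(length(sp), prob = 1 / paralogMean)
    prot <- unlist(mapply(function(s, np)
      paste0(s, "|", famIds[j], "|", seq_len(np)),
      sp, nPar, SIMPLIFY = FALSE), use.names = FALSE)
    families[[j]] <- prot
    proteinSpecies[[j]] <- setNames(rep(sp, nPar), prot)
  }
  names(families) <- famIds
  names(gt$gainNode) <- famIds
  names(gt$lossBranches) <- famIds
  names(gt$survivors) <- famIds
  ft <- new("FamilyTable", families = families,
            proteinSpecies = unlist(unname(proteinSpecies)),
            source = "simulated", cValue = NA_real_)
  list(familyTable = ft, groundTruth = gt)
}

#' Plant term annotations with phylostratum-concentrated enrichment
#'
#' Builds a protein-level annotation set in which chosen terms are
#' concentrated among the families gained at chosen phylostrata of one focal
#' lineage: a family gained at the planted phylostratum receives the term
#' with probability `rateEnriched`, any other family with probability
#' `rateBackground`; a receiving family's every protein carries the term.
#' Additional background terms are scattered uniformly over families at
#' `backgroundRate`, providing the unplanted noise floor.
#'
#' @param fams the [FamilyTable-class] the events were computed from.
#' @param ev an [EventTable-class] for one focal lineage.
#' @param planted data.frame with columns `term`, `ps`, `rateEnriched`,
#'   `rateBackground`; may have zero rows.
#' @param nBackgroundTerms number of extra uniformly scattered terms
#'   (named `bg1..bgM`).
#' @param backgroundRate per-family probability of carrying each background
#'   term.
#' @param seed optional integer seed.
#' @return Named list protein id -> character vector of terms, suitable for
#'   [transferAnnotations()].
#' @export
plantAnnotations <- function(fams, ev, planted = NULL, nBackgroundTerms = 0L,
                             backgroundRate = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(planted))
    planted <- data.frame(term = character(0), ps = integer(0),
                          rateEnriched = numeric(0),
                          rateBackground = numeric(0))
  if (nrow(planted)) {
    if (any(planted$ps < 1L | planted$ps > ev@nPs))
      stop("planted phylostratum out of lineage range (1..", ev@nPs, ")")
    if (any(planted$rateEnriched < 0 | planted$rateEnriched > 1 |
            planted$rateBackground < 0 | planted$rateBackground > 1))
      stop("planted rates must lie in [0, 1]")
  }
  ids <- familyIDs(fams)
  gainPs <- ev@events$gain_ps[match(ids, ev@events$family)]
  famTerms <- rep(list(character(0)), length(ids))
  for (r in seq_len(nrow(planted))) {
    atPs <- !is.na(gainPs) & gainPs == planted$ps[r]
    p <- ifelse(atPs, planted$rateEnriched[r], planted$rateBackground[r])
    hit <- stats::runif(length(ids)) < p
    famTerms[hit] <- lapply(famTerms[hit], c, planted$term[r])
  }
  if (nBackgroundTerms > 0L) {
    for (b in seq_len(nBackgroundTerms)) {
      hit <- stats::runif(length(ids)) < backgroundRate
      famTerms[hit] <- lapply(famTerms[hit], c, paste0("bg", b))
    }
  }
  out <- list()
  for (j in seq_along(ids)) {
    if (!length(famTerms[[j]])) next
    for (p in fams@families[[j]]) out[[p]] <- famTerms[[j]]
  }
  out
}

#' Write a simulated dataset as an on-disk fixture bundle
#'
#' Writes the tree (Newick), the cluster partition in both supported dialects
#' (MMseqs2 two-column TSV with the first member as representative, and MCL
#' one-cluster-per-line), the protein->species map, the protein->term
#' annotation table and the ground-truth table. The bundle round-trips
#' through the package readers without loss.
#'
#' @param phy a [Phylogeny-class]
#' @param fams a [FamilyTable-class] with species attached.
#' @param annotations named list protein id -> terms (may be empty).
#' @param groundTruth optional ground-truth list from [simulateFamilies()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the written file paths.
#' @export
writeFixtureBundle <- function(phy, fams, annotations = list(),
                               groundTruth = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    tree = file.path(dir, "tree.nwk"),
    mmseqs = file.path(dir, "clusters_mmseqs.tsv"),
    mcl = file.path(dir, "clusters_mcl.txt"),
    species = file.path(dir, "species_map.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  writeNewick(phy, paths[["tree"]])
  mm <- do.call(rbind, lapply(fams@families, function(m)
    cbind(rep(m[1L], length(m)), m)))
  utils::write.table(mm, paths[["mmseqs"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(vapply(fams@families, paste, "", collapse = "\t"),
             paths[["mcl"]])
  utils::write.table(
    data.frame(protein = names(fams@proteinSpecies),
               species = unname(fams@proteinSpecies)),
    paths[["species"]], sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  annLines <- vapply(names(annotations), function(p)
    paste0(p, "\t", paste(annotations[[p]], collapse = ",")), "")
  writeLines(annLines, paths[["annotations"]])
  if (!is.null(groundTruth)) {
    utils::write.table(
      data.frame(
        family_id = names(groundTruth$gainNode),
        gain_node_id = unname(groundTruth$gainNode),
        loss_branch_child_ids = vapply(groundTruth$lossBranches, paste, "",
                                       collapse = ","),
        surviving_species = vapply(groundTruth$survivors, function(s)
          paste(phy@labels[s], collapse = ","), "")
      ),
      paths[["ground_truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "ground_truth"]
  }
  paths
}
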