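#' Gene-family content profile along a focal lineage
#'
#' Per phylostratum i: the number of families gained, the number lost and the
#' ancestral content `content_i = content_{i-1} + gains_i - losses_i`
#' (with `content_0 = 0`), i.e. the number of families gained at or before i
#' and not yet lost. The terminal content equals the number of families whose
#' species set contains the focal species.
#'
#' @param ev an [EventTable-class]
#' @param lineage optional [FocalLineage-class] supplying phylostratum names.
#' @return data.frame with columns `ps_index`, `ps_name`, `gains`, `losses`,
#'   `content`.
#' @export
contentProfile <- function(ev, lineage = NULL) {
  n <- ev@nPs
  e <- ev@events
  has <- !is.na(e$loss_ps)
  if (any(has & e$loss_ps <= e$gain_ps + 1L))
    stop("invalid event: loss_ps must exceed gain_ps by at least 2")
  gains <- tabulate(e$gain_ps, nbins = n)
  losses <- tabulate(e$loss_ps[has], nbins = n)
  psNames <- if (is.null(lineage)) paste0("ps", seq_len(n)) else lineage@psNames
  data.frame(
    ps_index = seq_len(n),
    ps_name = psNames,
    gains = gains,
    losses = losses,
    content = cumsum(gains - losses)
  )
}

#' Ancestral gene-family content at every tree node
#'
#' From the whole-tree union of events: the content at node v is the number
#' of families whose gain node is ancestral to (or equals) v and whose member
#' species still occur in the subtree of v. At a leaf this specializes to the
#' number of families containing that species.
#'
#' @param un a [UnionEvents-class]
#' @param phy the [Phylogeny-class] the union was computed on.
#' @return Integer vector of length `nNodes(phy)`: family count per node id.
#' @export
ancestralContent <- function(un, phy) {
  counts <- integer(nNodes(phy))
  # ancestor chain per node, computed once
  for (j in seq_along(un@gainNode)) {
    g <- un@gainNode[[j]]
    lv <- un@familyLeaves[[j]]
    # nodes in subtree(g) whose subtree still holds a member
    stack <- g
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      counts[v] <- counts[v] + 1L
      for (w in phy@children[[v]])
        if (any(lv %in% phy@descLeaves[[w]])) stack <- c(stack, w)
    }
  }
  counts
}

#' Log2 gain/loss ratio profile
#'
#' Adds `log2_ratio = log2(gains/losses)` per phylostratum. The ratio is
#' undefined — reported `NA`, not infinite and not pseudocounted — whenever
#' either count is zero or the phylostratum lies before the third, where a
#' loss cannot yet have occurred; the raw counts are always kept alongside so
#' no information is lost.
#'
#' @param profile a content profile from [contentProfile()].
#' @return The profile with a `log2_ratio` column appended.
#' @export
log2GainLossRatio <- function(profile) {
  defined <- profile$gains > 0L & profile$losses > 0L & profile$ps_index >= 3L
  profile$log2_ratio <- ifelse(defined,
                               log2(profile$gains / profile$losses),
                               NA_real_)
  profile
}

#' Phylostratum range of maximal gene-family content
#'
#' @param profile a content profile from [contentProfile()].
#' @return Integer vector `c(first, last)`: the inclusive phylostratum range
#'   over which the maximum content is attained (ties spanned).
#' @export
peakRange <- function(profile) {
  if (!nrow(profile)) stop("profile must be non-empty")
  at <- which(profile$content == max(profile$content))
  c(profile$ps_index[min(at)], profile$ps_index[max(at)])
}

#' Profile export with ratio and peak flag
#'
#' @param ev an [EventTable-class]
#' @param lineage a [FocalLineage-class]
#' @param cValue c-value label of the clustering run.
#' @param file optional output TSV path.
#' @return data.frame with columns `focal_species`, `c_value`, `ps_index`,
#'   `ps_name`, `gains`, `losses`, `content`, `log2_ratio`, `peak_flag`.
#' @export
profileExport <- function(ev, lineage = NULL, cValue = NA_real_, file = NULL) {
  pr <- log2GainLossRatio(contentProfile(ev, lineage))
  pk <- peakRange(pr)
  df <- data.frame(
    focal_species = ev@focal,
    c_value = cValue,
    pr[, c("ps_index", "ps_name", "gains", "losses", "content")],
    log2_ratio = ifelse(is.na(pr$log2_ratio), "",
                        format(pr$log2_ratio, digits = 10)),
    peak_flag = pr$ps_index >= pk[1L] & pr$ps_index <= pk[2L],
    stringsAsFactors = FALSE
  )
  if (!is.null(file))
    utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}
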