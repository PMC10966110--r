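# Independent oracles and fixture builders used across the suite.

# Brute-force Dollo reconstruction: enumerate every candidate single-gain
# node whose subtree covers the member leaves, label presence by the
# recursive any-descendant rule, count loss branches (present parent ->
# absent child), and keep the minimum-loss solution. Independent of the
# LCA closed form used by the package.
dolloOracle <- function(phy, memberLeaves) {
  nn <- nNodes(phy)
  label <- function(g) {
    present <- logical(nn)
    rec <- function(v) {
      if (phy@isLeaf[v]) present[v] <<- v %in% memberLeaves
      else {
        for (w in phy@children[[v]]) rec(w)
        present[v] <<- any(present[phy@children[[v]]])
      }
    }
    rec(g)
    loss <- integer(0)
    for (v in seq_len(nn)) {
      if (!present[v]) next
      for (w in phy@children[[v]]) if (!present[w]) loss <- c(loss, w)
    }
    list(present = present, loss = loss)
  }
  best <- NULL
  for (g in seq_len(nn)) {
    if (!all(memberLeaves %in% phy@descLeaves[[g]])) next
    lab <- label(g)
    if (is.null(best) || length(lab$loss) < best$nloss)
      best <- list(gain = g, nloss = length(lab$loss),
                   loss = sort(lab$loss), present = lab$present)
  }
  best
}

# Loss phylostratum read off the oracle's presence labeling along a path:
# the first position after the gain at which the family is absent.
oracleLossPs <- function(oracle, lineage) {
  gi <- match(oracle$gain, lineage@path)
  if (is.na(gi)) return(NA_integer_)
  n <- length(lineage@path)
  if (gi < n) for (i in (gi + 1L):n) {
    if (!oracle$present[lineage@path[i]]) return(i)
  }
  NA_integer_
}

# Hypergeometric pmf from log binomial coefficients (no dhyper), and the
# minimum-likelihood two-sided p by direct enumeration.
hyperOracle <- function(k, K, n, N) {
  lo <- max(0L, n + K - N); hi <- min(n, K)
  x <- lo:hi
  lp <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  pmf <- exp(lp)
  obs <- pmf[match(k, x)]
  min(1, sum(pmf[pmf <= obs * (1 + 1e-07)]))
}

# FamilyTable from a named list of species-prefixed protein ids.
makeFamilies <- function(lst, source = "test") {
  ft <- new("FamilyTable", families = lst,
            proteinSpecies = stats::setNames(character(0), character(0)),
            source = source, cValue = NA_real_)
  attachSpecies(ft, convention = "prefix")
}

# Minimal EventTable built directly from vectors (for enrichment tests).
makeEvents <- function(family, gain_ps, loss_ps, focal = "X", nPs = 5L) {
  new("EventTable",
      events = data.frame(family = family, gain_ps = as.integer(gain_ps),
                          gain_node = rep(NA_integer_, length(family)),
                          loss_ps = as.integer(loss_ps),
                          loss_node = rep(NA_integer_, length(family)),
                          stringsAsFactors = FALSE),
      focal = focal, nPs = as.integer(nPs),
      excluded = data.frame(family = character(0), reason = character(0),
                            stringsAsFactors = FALSE))
}

# AnnotationMap with directly supplied family terms.
makeAnnotation <- function(familyTerms, mode = "any") {
  new("AnnotationMap", proteinTerms = list(), familyTerms = familyTerms,
      mode = mode)
}

# All non-empty leaf subsets of a tree, as lists of leaf-id vectors.
allLeafPatterns <- function(nLeaves) {
  unlist(lapply(seq_len(2^nLeaves - 1), function(m)
    list(which(bitwAnd(m, 2^(seq_len(nLeaves) - 1)) > 0))), recursive = FALSE)
}
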