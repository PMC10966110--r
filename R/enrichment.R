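#' Two-tailed hypergeometric test (minimum-likelihood convention)
#'
#' Exact two-sided p-value for drawing `k` annotated families in a sample of
#' `n` from a universe of `N` families of which `K` are annotated: the sum of
#' the probabilities of all achievable outcomes whose point probability does
#' not exceed that of the observed one (the standard exact two-sided
#' convention for Fisher-type tests, with the usual relative tolerance when
#' comparing point probabilities).
#'
#' @param k observed annotated families in the sample.
#' @param K annotated families in the universe.
#' @param n sample size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @examples
#' hypergeomTwoSided(4, 4, 5, 10)   # 12/252
#' @export
hypergeomTwoSided <- function(k, K, n, N) {
  .checkCounts(k, K, n, N)
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  x <- lo:hi
  pmf <- stats::dhyper(x, K, N - K, n)
  obs <- pmf[match(k, x)]
  # relative tolerance guards against ties broken by floating-point noise
  min(1, sum(pmf[pmf <= obs * (1 + 1e-07)]))
}

.checkCounts <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N ||
      k > min(n, K) || k < max(0, n + K - N))
    stop("invalid contingency counts: need max(0, n+K-N) <= k <= min(n, K), ",
         "K <= N, n <= N")
  invisible(TRUE)
}

#' Log2 odds ratio with Haldane-Anscombe correction
#'
#' Effect size of the 2x2 term-by-phylostratum table, `log2` of the odds
#' ratio after adding 0.5 to each of the four cells so tables with `k = 0` or
#' `k = n` stay finite. Antisymmetric under swapping the annotated and
#' unannotated columns.
#'
#' @inheritParams hypergeomTwoSided
#' @return Real log2 odds ratio.
#' @examples
#' logOdds(4, 4, 5, 10)   # log2(33)
#' @export
logOdds <- function(k, K, n, N) {
  .checkCounts(k, K, n, N)
  log2(((k + 0.5) * (N - K - n + k + 0.5)) /
       ((K - k + 0.5) * (n - k + 0.5)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a
#' named operation so the correction scope applied by [enrich()] is explicit.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-phylostratum functional enrichment of gained or lost families
#'
#' For one focal lineage and one clustering run, tests every (term,
#' phylostratum) pair for over- or under-representation of the term among the
#' families with a gain (or loss) event at that phylostratum, against the
#' lineage-wide background. The universe is the family set carrying an event
#' of the requested direction: for gains, all families of the event table
#' (or, under `universe = "lost_only"`, only families that also have a loss
#' event); for losses, always the families with a loss event. Records with
#' `k = 0` are retained — depletion is testable under the two-sided test —
#' and unannotated families carry the reserved term `"NA"`, which is itself
#' testable.
#'
#' Benjamini-Hochberg correction is applied across all (term, phylostratum)
#' pairs of the run and direction jointly (default), or within each term
#' across phylostrata under `bhScope = "per_term"`.
#'
#' @param ev an [EventTable-class]
#' @param ann an [AnnotationMap-class] for the same family table.
#' @param direction `"gain"` or `"loss"`.
#' @param alpha significance threshold applied to the adjusted p-values.
#' @param universe `"all"` or `"lost_only"`. For `direction = "loss"` the
#'   universe is the loss universe regardless.
#' @param bhScope `"joint"` (default) or `"per_term"`.
#' @return data.frame with one row per tested (term, phylostratum) pair:
#'   `term`, `ps_index`, `direction`, `k`, `n`, `K`, `N`, `log_odds`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
enrich <- function(ev, ann, direction = c("gain", "loss"), alpha = 0.05,
                   universe = c("all", "lost_only"),
                   bhScope = c("joint", "per_term")) {
  direction <- match.arg(direction)
  universe <- match.arg(universe)
  bhScope <- match.arg(bhScope)
  e <- ev@events
  if (direction == "loss" || universe == "lost_only")
    e <- e[!is.na(e$loss_ps), , drop = FALSE]
  famTerms <- ann@familyTerms[e$family]
  N <- nrow(e)
  if (!N)
    return(data.frame(term = character(0), ps_index = integer(0),
                      direction = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), log_odds = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  Ktab <- table(unlist(famTerms, use.names = FALSE))
  eventPs <- if (direction == "gain") e$gain_ps else e$loss_ps
  recs <- list()
  for (ps in sort(unique(eventPs))) {
    inPs <- eventPs == ps
    n <- sum(inPs)
    kt <- table(unlist(famTerms[inPs], use.names = FALSE))
    for (term in names(Ktab)) {
      k <- if (term %in% names(kt)) as.integer(kt[[term]]) else 0L
      K <- as.integer(Ktab[[term]])
      recs[[length(recs) + 1L]] <- data.frame(
        term = term, ps_index = as.integer(ps), direction = direction,
        k = k, n = n, K = K, N = N,
        log_odds = logOdds(k, K, n, N),
        p_raw = hypergeomTwoSided(k, K, n, N),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  out$p_adj <- if (bhScope == "joint") bhAdjust(out$p_raw) else
    stats::ave(out$p_raw, out$term, FUN = bhAdjust)
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Frequency of terms with at least one significant phylostratum
#'
#' A term counts as enriched when at least one phylostratum shows a
#' significant record; the frequency is the percentage of tested terms that
#' are enriched. Summarizes the recoverable signal of one
#' (focal, c value, direction) run.
#'
#' @param records output of [enrich()].
#' @param termsTested optional total number of tested terms; defaults to the
#'   number of distinct terms in `records`.
#' @return data.frame with columns `terms_tested`, `terms_enriched`,
#'   `frequency_pct` (`NA` when no terms were tested).
#' @export
enrichmentFrequency <- function(records, termsTested = NULL) {
  terms <- unique(records$term)
  if (is.null(termsTested)) termsTested <- length(terms)
  enriched <- length(unique(records$term[records$significant]))
  data.frame(
    terms_tested = termsTested,
    terms_enriched = enriched,
    frequency_pct = if (termsTested == 0L) NA_real_ else
      100 * enriched / termsTested
  )
}

#' Gain-versus-loss enrichment balance
#'
#' Compares the number of significantly enriched terms among gains and among
#' losses; meaningful when both record sets were computed on the lost-only
#' universe (families carrying a loss event), so the same family set backs
#' both directions.
#'
#' @param recordsGain,recordsLoss outputs of [enrich()] for the two
#'   directions.
#' @return data.frame with columns `gain_enriched`, `loss_enriched`, `ratio`
#'   (`NA` when no term is enriched among losses).
#' @export
gainLossBalance <- function(recordsGain, recordsLoss) {
  g <- length(unique(recordsGain$term[recordsGain$significant]))
  l <- length(unique(recordsLoss$term[recordsLoss$significant]))
  data.frame(
    gain_enriched = g,
    loss_enriched = l,
    ratio = if (l == 0L) NA_real_ else g / l
  )
}
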