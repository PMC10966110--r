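test_that("two-sided hypergeometric matches full pmf enumeration on worked tables", {
  # pmf over x in 0..4 is (6, 60, 120, 60, 6)/252; outcomes with
  # P(x) <= P(4) are x in {0, 4}, so p = 12/252
  expect_equal(hypergeomTwoSided(4, 4, 5, 10), 12 / 252, tolerance = 1e-12)
  expect_equal(hypergeomTwoSided(5, 5, 5, 10), 2 / 252, tolerance = 1e-12)
  expect_equal(hypergeomTwoSided(5, 5, 5, 5), 1)
  expect_error(hypergeomTwoSided(6, 5, 5, 10), "invalid contingency")
})

test_that("two-sided p agrees with fisher.test and dominates the upper tail", {
  set.seed(17)
  for (rep in 1:60) {
    N <- sample(5:45, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    rng <- max(0, n + K - N):min(n, K)
    k <- rng[sample.int(length(rng), 1)]
    p <- hypergeomTwoSided(k, K, n, N)
    tab <- matrix(c(k, n - k, K - k, N - K - n + k), 2)
    expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-09)
    # the two-sided p can never undercut the smaller one-sided tail
    upper <- sum(stats::dhyper(k:min(n, K), K, N - K, n))
    lower <- sum(stats::dhyper(max(0, n + K - N):k, K, N - K, n))
    expect_gte(p + 1e-12, min(upper, lower))
  }
})

test_that("log-odds uses the Haldane correction and is antisymmetric", {
  expect_equal(logOdds(2, 4, 5, 10), 0)
  expect_equal(logOdds(4, 4, 5, 10), log2(33))
  expect_equal(logOdds(0, 4, 5, 10), -log2(33))
  set.seed(23)
  for (rep in 1:30) {
    N <- sample(4:40, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    rng <- max(0, n + K - N):min(n, K)
    k <- rng[sample.int(length(rng), 1)]
    # swapping the annotated/unannotated columns negates the value
    expect_equal(logOdds(k, K, n, N), -logOdds(n - k, N - K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up formula and preserves order", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(c(1, 1)), c(1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(29)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), 1:50)  # monotone in p
  expect_equal(bhAdjust(rep(0.2, 10)), rep(0.2, 10))  # idempotent on ties
})

test_that("enrich composes counts, p-values and effect sizes per (term, ps)", {
  # universe: 10 gained families; term T carried by 4, all gained at ps2
  # (n = 5 there); remaining families carry only the reserved NA term
  fams <- paste0("f", 1:10)
  gain <- c(rep(2L, 5), c(1L, 1L, 3L, 4L, 4L))
  terms <- c(as.list(rep("T", 4)), as.list(rep("NA", 6)))
  names(terms) <- fams
  ev <- makeEvents(fams, gain, rep(NA_integer_, 10), nPs = 5L)
  rec <- enrich(ev, makeAnnotation(terms), "gain", alpha = 0.05)
  r <- rec[rec$term == "T" & rec$ps_index == 2L, ]
  expect_equal(r$k, 4L); expect_equal(r$n, 5L)
  expect_equal(r$K, 4L); expect_equal(r$N, 10L)
  expect_equal(r$p_raw, 12 / 252, tolerance = 1e-09)
  expect_equal(r$log_odds, log2(33), tolerance = 1e-09)
  # k = 0 records are retained (depletion is testable)
  expect_true(nrow(rec[rec$term == "T" & rec$ps_index == 1L, ]) == 1L)
  expect_equal(rec$k[rec$term == "T" & rec$ps_index == 1L], 0L)
  # the reserved NA pseudo-term is itself tested
  expect_true("NA" %in% rec$term)
  # BH is applied across all pairs jointly
  expect_equal(rec$p_adj, bhAdjust(rec$p_raw))
})

test_that("terms absent from the universe produce no records", {
  ev <- makeEvents(c("f1", "f2"), c(1L, 1L), c(NA_integer_, NA_integer_),
                   nPs = 4L)
  rec <- enrich(ev, makeAnnotation(list(f1 = "T", f2 = "T")), "gain")
  expect_setequal(unique(rec$term), "T")
})

test_that("loss direction and lost_only universe restrict to families with a loss", {
  fams <- paste0("f", 1:8)
  ev <- makeEvents(fams, gain_ps = rep(1L, 8),
                   loss_ps = c(3L, 3L, 4L, 4L, NA, NA, NA, NA), nPs = 5L)
  terms <- setNames(as.list(rep("T", 8)), fams)
  recLoss <- enrich(ev, makeAnnotation(terms), "loss")
  expect_true(all(recLoss$N == 4L))
  recGainAll <- enrich(ev, makeAnnotation(terms), "gain", universe = "all")
  expect_true(all(recGainAll$N == 8L))
  recGainLost <- enrich(ev, makeAnnotation(terms), "gain",
                        universe = "lost_only")
  expect_true(all(recGainLost$N == 4L))
})

test_that("per-term BH scope adjusts within each term", {
  fams <- paste0("f", 1:12)
  set.seed(31)
  ev <- makeEvents(fams, gain_ps = rep(1:3, 4),
                   loss_ps = rep(NA_integer_, 12), nPs = 5L)
  terms <- setNames(lapply(1:12, function(i)
    sample(c("T1", "T2"), 1)), fams)
  rec <- enrich(ev, makeAnnotation(terms), "gain", bhScope = "per_term")
  for (tm in unique(rec$term)) {
    sel <- rec$term == tm
    expect_equal(rec$p_adj[sel], bhAdjust(rec$p_raw[sel]))
  }
})

test_that("enrichment frequency counts terms with >= 1 significant stratum", {
  rec <- data.frame(term = c("a", "a", "b", "c"),
                    significant = c(TRUE, TRUE, FALSE, FALSE))
  s <- enrichmentFrequency(rec)
  expect_equal(s$terms_tested, 3L)
  expect_equal(s$terms_enriched, 1L)
  expect_equal(s$frequency_pct, 100 / 3)
  expect_equal(enrichmentFrequency(rec[rec$term == "z", ])$frequency_pct,
               NA_real_)
  recAll <- data.frame(term = c("a", "b"), significant = c(TRUE, TRUE))
  expect_equal(enrichmentFrequency(recAll)$frequency_pct, 100)
})

test_that("gain/loss balance reports counts and their ratio", {
  mk <- function(terms, sig) data.frame(term = terms, significant = sig)
  b <- gainLossBalance(mk(paste0("g", 1:10), rep(TRUE, 10)),
                       mk(paste0("l", 1:4), rep(TRUE, 4)))
  expect_equal(b$ratio, 2.5)
  b0 <- gainLossBalance(mk("x", FALSE), mk("y", FALSE))
  expect_equal(b0$gain_enriched, 0L)
  expect_true(is.na(b0$ratio))
  same <- mk(c("a", "b"), c(TRUE, TRUE))
  expect_equal(gainLossBalance(same, same)$ratio, 1)
})

test_that("planted enrichment is recovered and a null term is not", {
  phy <- simulateTree(12, "caterpillar")
  lin <- focalLineage(phy, "S1")
  w <- rep(0.05, nNodes(phy))
  w[lin@path[3]] <- 1
  sim <- simulateFamilies(phy, 150, lossProb = 0.1, gainWeights = w,
                          seed = 61)
  fams <- sim$familyTable
  ev <- lineageEvents(fams, phy, lin)
  ann <- plantAnnotations(fams, ev,
    planted = data.frame(term = "GO:planted", ps = 3L,
                         rateEnriched = 0.9, rateBackground = 0.05),
    nBackgroundTerms = 3, backgroundRate = 0.2, seed = 62)
  rec <- enrich(ev, transferAnnotations(fams, ann, "any"), "gain")
  hit <- rec[rec$term == "GO:planted" & rec$ps_index == 3L, ]
  expect_true(hit$significant)
  expect_gt(hit$log_odds, 0)
})
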