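---
title: "Dollo-parsimony phylostratigraphy: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dollo-parsimony phylostratigraphy: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloDollo)
```

# The model

phyloDollo traces the evolutionary history of gene families — clusters of
homologous proteins — on a rooted species phylogeny. The tree is purely
topological: branch lengths, if present in the input Newick, are discarded,
because the phylostratigraphic map is ordinal. For a focal species the
root-to-tip node path defines phylostrata ps1..psN; every analysis in the
package is indexed by these positions, never by time.

## Dollo reconstruction

The reconstruction principle is Dollo parsimony: a family is gained exactly
once and may subsequently be lost any number of times, but never regained.
Under this single-origin constraint the gain node of a family with species
set $S$ is forced: any candidate origin must be ancestral to all of $S$, and
among those candidates the last common ancestor $\mathrm{lca}(S)$ is the
unique minimum-loss choice — moving the origin one node rootward adds at
least one loss for every sibling subtree that contains no member. The
package therefore computes the gain node in closed form as the LCA, and the
test suite keeps an explicit brute-force reconstruction (enumerate all
single-gain candidates, label presence recursively, count loss branches,
minimize) as an independent oracle; the two agree exhaustively on every
rooted bifurcating shape with up to six leaves and every presence/absence
pattern.

Presence at a path node $v$ likewise has a closed form: $v$ descends from
(or equals) the gain node and the subtree of $v$ still contains a member
species. Because subtree leaf sets shrink monotonically along the path, the
loss phylostratum is simply the first absent position after the gain.

Two structural facts follow and are enforced as class invariants:

* a loss can occur at the earliest two positions after the gain
  (`loss_ps >= gain_ps + 2`), hence never before ps3;
* a reconstruction that would place the loss immediately after the gain can
  only arise when the gain node is a polytomy — the family then belongs to a
  side branch of the unresolved node, not to the focal lineage. Such
  families are excluded from the lineage and reported in a side-channel
  (`excludedFamilies()`) rather than silently dropped, so run logs can
  account for every input family.

## Content and ratio profiles

Per-lineage content cumulates events,
$c_i = c_{i-1} + \mathrm{gains}_i - \mathrm{losses}_i$, and telescopes to
the number of retained families containing the focal species — a
conservation law the tests verify on every simulated dataset. Whole-tree
ancestral content evaluates the same presence formula per node from the
union of events over all lineages; on any focal path the two computations
coincide, which the suite checks directly. The `log2(gains/losses)` ratio is
reported only where both counts are positive and `ps >= 3`; we deliberately
emit `NA` rather than pseudocounted or infinite values, keeping the raw
counts alongside so no information is lost.

## Functional enrichment

Annotations are transferred from proteins to families either by the
any-member rule or by a stringent rule requiring at least 50 % of member
proteins to carry the term. The threshold is inclusive (exactly half
qualifies), and all member proteins count in the denominator whether or not
they have any annotation — the conservative reading where the convention is
genuinely open. Families left without terms receive the reserved pseudo-term
`"NA"`, so unannotated families participate in contingency totals and the
`"NA"` class is itself testable.

Each (term, phylostratum) pair is tested with the exact two-tailed
hypergeometric test under the minimum-likelihood convention: the p-value
sums the probabilities of all achievable outcomes whose point probability
does not exceed the observed one (with the customary $1 + 10^{-7}$ relative
tolerance when comparing point probabilities). This is the standard exact
two-sided convention for Fisher-type tests, and the implementation agrees
with `fisher.test()` on random tables and with direct pmf enumeration on
every table up to $N = 60$. Effect sizes are log2 odds ratios with the
Haldane–Anscombe +0.5 correction in all four cells, finite for boundary
tables and antisymmetric under swapping the annotated and unannotated
columns. Records with $k = 0$ are retained, since depletion is a legitimate
two-sided outcome.

Multiple-testing correction is Benjamini–Hochberg (via `p.adjust`). The
correction pool is a design choice the literature leaves open: the default
corrects across all (term, phylostratum) pairs of one run and direction
jointly — the conservative reading — with `bhScope = "per_term"` available
to correct within each term across phylostrata. Significance defaults to
`p_adj < 0.05`.

The enrichment universe is the family set carrying an event of the tested
direction: all families of the lineage for gains, families with a loss event
for losses. `universe = "lost_only"` restricts the gain universe to families
that also have a loss, so `gainLossBalance()` compares both directions over
the same family set.

# The synthetic-data generator

`simulateFamilies()` draws, per family, a gain node (uniform over nodes by
default, or weighted), then prunes each branch strictly below it
independently with probability $q$; pruned subtrees are not revisited, so
the generative process is Dollo-compatible by construction — no regain, no
horizontal transfer — and parameter recovery is well-posed. Families losing
every species are redrawn so the requested family count is exact (the
regeneration count is recorded in the ground truth). Each surviving species
contributes $1 + \mathrm{Geom}(1/m)$ proteins, i.e. a geometric paralog
count with mean $m \ge 1$ (default 1.5, a modest paralog load typical of
compact genomes). `plantAnnotations()` adds terms concentrated among
families gained at a chosen phylostratum (rate $r_e$ there, $r_b$
elsewhere) over a background of uniformly scattered terms.

What the generator emulates — single-origin families, independent branch
losses, at least one protein per surviving species, term–phylostratum
concentration — is exactly the inference model's assumption set. What it
does not emulate: multiple origins and horizontal transfer (for a multiply
acquired feature Dollo places the gain at the LCA of all carriers, rootward
of every true acquisition), annotation errors correlated with family size,
and clustering artifacts such as fused or split families. Passing
recovery tests therefore validate the reconstruction machinery, not the
upstream clustering, and real-data gains near the root should be read with
the multiple-origin caveat in mind.

An identifiability limit is intrinsic rather than a defect: when losses
confine the survivors to one child clade of the true gain node, the LCA of
the survivors is shallower than the truth, and no method could do better
from presence/absence alone. The simulator's ground truth lets the tests
quantify this: recovery is exact precisely on the families whose surviving
set still witnesses the gain node.

# Parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| transfer mode | `transferAnnotations()` | `"any"` | preserves sparse functional information; `"fraction"` (≥ 50 %, inclusive) trades power for precision |
| `alpha` | `enrich()` | 0.05 | conventional FDR level, applied to adjusted p |
| BH scope | `enrich()` | `"joint"` | conservative pool over all (term, ps) pairs |
| universe | `enrich()` | `"all"` | lineage-wide background; `"lost_only"` for gain-vs-loss balance |
| `lossProb` (q) | simulator | 0.1 | per-branch loss probability; moderate turnover |
| `paralogMean` | simulator | 1.5 | mean proteins per surviving species (geometric) |
| c grid | `cGrid()` | 0.0–0.8 by 0.1 | the nine standard alignment-coverage stringencies of the clustering runs |

# Numerical choices and degenerate inputs

* Point-probability comparisons in the two-sided test use a $1 + 10^{-7}$
  relative tolerance; p-values are clamped to 1.
* `peakRange()` spans ties of the content maximum; an all-zero profile
  peaks over the full range by the same rule.
* Polytomies are legal everywhere (consensus trees are often unresolved);
  no resolution is attempted, and the immediate-loss exclusion rule is the
  only place where polytomies behave differently from bifurcating trees.
* Node identity is positional (integer ids fixed at parse time); all
  cross-object references use these ids.
* Degenerate inputs fail loudly: duplicate leaf names, proteins in two
  clusters, unresolvable species, foreign node ids and malformed tables
  raise errors naming the offender.
* GO terms are treated as flat labels — no ancestor propagation — taking
  the annotation export as-is.

# Problem sizes used by the checks

The exhaustive reconstruction checks cover all rooted bifurcating topologies
with 4–6 leaves (15, 105 and 945 shapes), all $2^n - 1$ presence patterns
and every focal leaf; the exact-test enumeration covers all ~635 000 tables
with $N \le 60$. Calibration experiments use a 12-leaf caterpillar tree with
150 families and 100 seeded replicates per regime — sizes at which the
planted signal (rate 0.8 at the target phylostratum vs 0.1 background,
$n \ge 30$ event families) is comfortably detectable while a null scatter
stays at the nominal false-positive level. These sizes are the package's
reference experiment; the functions themselves have no built-in limits
beyond memory.

# Known limitations

* Dollo parsimony cannot localize multiply acquired features; it reports
  their LCA.
* Probabilistic gene-content models (birth–death likelihoods, gene-tree
  reconciliation) are out of scope; the package is deliberately
  parsimony-based and deterministic given its inputs.
* Enrichment treats families as exchangeable units; family size does not
  weight the test.
* The pipeline starts from finished clusters — sequence similarity search,
  clustering and annotation are upstream tools' responsibility.
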