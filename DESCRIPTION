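Package: phyloDollo
Title: Dollo-Parsimony Phylostratigraphy of Gene-Family Gain and Loss
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Maps gene-family (protein cluster) gains and losses onto a rooted
    species phylogeny under Dollo parsimony. For any focal species the
    root-to-tip path defines ordinal phylostrata; each family is assigned a
    gain phylostratum (the last common ancestor of its member species) and,
    where the focal species lacks the family, a loss phylostratum. The package
    reconstructs ancestral gene-family content per phylostratum and per tree
    node, computes log2 gain/loss ratio profiles, and tests functional terms
    (COG categories or GO identifiers) for two-tailed hypergeometric
    enrichment among gained or lost families per phylostratum with
    Benjamini-Hochberg correction. Cluster membership is read in MMseqs2
    createtsv or MCL dialects. A seeded simulator generates Dollo-compatible
    family evolution on random or caterpillar trees, with planted
    term-phylostratum enrichment, so the whole pipeline can be exercised and
    calibrated without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
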