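Package: polytomyprobe
Title: Is a Contested Phylogenetic Branch Resolvable? Gene-Tree Census,
    Concordance, Introgression Tests and Polytomy Topology Tests
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for asking whether a short internal branch of
    a species tree (the motivating case is the elephant/hyrax/sea-cow split
    within Paenungulata) is genuinely resolvable or is effectively a
    polytomy. Classifies per-gene trees into the three resolutions of a
    focal lineage triplet, computes gene and site concordance factors,
    internode certainty (IC/ICA), a multispecies-coalescent triplet summary
    (majority topology, coalescent-unit branch length, local posterior
    probability, gene-tree bootstrap), the discordant-count and branch-length
    introgression tests with Holm correction, per-gene RELL-family and
    approximately unbiased tree topology tests against the polytomy, codon
    alignment hygiene (complete-codon filtering and indel-flank trimming),
    and a seeded multispecies-coalescent simulator with an introgression
    pulse that generates the synthetic datasets the test-suite and worked
    examples run on.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
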