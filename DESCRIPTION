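Package: coevosite
Title: Evolutionary Correlations Between Regulatory Sites in Aligned 3'UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies preferential conservation of miRNA seed-match sites
    in multi-species 3'UTR alignments and detects evolutionary correlations
    between pairs of sites. The background model is a Markov random field on
    the species phylogeny with hidden ancestral nodes, fitted to per-species
    and per-species-pair K-mer conservation frequencies; per-site conservation
    scores and per-pair couplings are inferred by maximum likelihood with
    exact message passing. Includes TargetScan-style seed-match scanning over
    stitched MAF alignments, dinucleotide-matched control seeds with
    conservation-matched biased bootstrap resampling, and Poisson/Skellam
    enrichment statistics over regulatory contexts (same 3'UTR, gene sets,
    miRNA networks), plus a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    Biostrings,
    IRanges,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
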