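Package: strainniche
Title: Host Niche-Association Analysis of Strain-Level Metagenomic Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Strain-level comparative analysis of gut microbiomes shared
    across host species (cats, dogs, humans). Computes Kimura 2-parameter
    distances from multiple sequence alignments of per-sample consensus
    strains with pairwise deletion, and from them a host coherence
    (niche-association) score quantifying how strongly a species' strains
    cluster by host. Also provides Bray-Curtis ordination with
    frequency-corrected principal coordinates and abundance-weighted taxon
    positions, one-factor permutational multivariate analysis of variance,
    rule-based screening of metagenome-assembled genomes (quality grading,
    Mash-distance genome-bin assignment, presence and host-sharing
    categories), antibiotic-resistance-gene hit filtering and drug-class
    aggregation, and a synthetic-data generator (K80 sequence evolution,
    host-structured abundance tables, planted screening fixtures) with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
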