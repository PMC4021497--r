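Package: symbiospec
Title: Host-Symbiont Association Specificity and Population Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies specialization in host-symbiont association networks
    from nodule-occupancy surveys and single-strain inoculation experiments.
    Implements the Paired Differences Index (PDI) on host-by-genotype link
    strength matrices with a multinomial resampling null model, genotype
    calling from aligned marker sequences (indel-column removal, haplotype
    collapsing, pairwise nucleotide differences), sequence-based population
    structure (within/between-population diversity, pairwise Phi-st and
    two-level hierarchical AMOVA with permutation tests), blocked-experiment
    response and effect specificity (per-block PDIs of fitness effects and
    nodule fitness components), genotype-mean fitness-feedback correlations
    and Mantel tests of genotype-phenotype association. Includes synthetic
    data generators that emulate multi-host nodule sampling, two-cluster
    haplotype alignments and a blocked inoculation experiment, so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
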