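Package: frogsynt
Title: Comparative Frog Genomics: Ancestral Synteny, Karyotype Rates,
    Nuclear Architecture, Recombination and Repeat Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for comparative chromosome-scale frog
    genomics. Infers conserved ancestral syntenic elements from
    cross-species ortholog placements, classifies chromosomal
    rearrangements (Robertsonian, end-to-end, reciprocal) against
    centromere geometry and tests rearrangement-rate hypotheses on a
    dated phylogeny, computes Hi-C nuclear-architecture statistics
    (Knight-Ruiz/ICE balancing, contact-based centromere inference, A/B
    compartments, Rabl SSD and CTP statistics, territory and inter-arm
    enrichment tests), estimates recombination landscapes from genetic
    maps with not-a-knot spline Marey smoothing, filters variant sites
    and measures residual heterozygosity under full-sib inbreeding, and
    clusters tandem-repeat monomers with regional enrichment ranking.
    Every analysis is exercisable on built-in synthetic data generators
    with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    IRanges,
    jsonlite,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
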