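Package: aspnet
Title: Allele-Specific Perturbation Analysis of Molecular Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects allele-specific co-perturbation (ASCP) and dys-perturbation
    (ASDP) of molecular interactions in a genotyped, expression-profiled segregant
    panel. Provides permutation-based eQTL and small-molecule response QTL mapping
    with Benjamini-Hochberg control, the Dys differential-correlation statistic with
    its permutation test, linkage-disequilibrium block detection, assembly of block-
    and compound-associated perturbed sub-networks over a typed interactome
    (protein-protein, protein-DNA, kinase-substrate and enzyme-enzyme layers),
    degree-preserving randomization tests of sub-network topology, hypergeometric
    drug-target enrichment, and a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
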