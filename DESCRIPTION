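Package: polyqtl
Title: Multiallelic Mixed-Model QTL Mapping for Polyploid Multiparental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) mapping in autopolyploid
    multiparental populations under biallelic and multiallelic marker models.
    Implements the Q+K mixed model with a realized-relationship kinship matrix,
    REML variance components estimated by spectral decomposition, and an
    EMMAX/P3D genome scan with generalized least-squares F-tests at every
    locus. Markers can be encoded as SNP allele dosages, as true
    identity-by-descent (founder) alleles, or as multiallelic haplotype blocks
    built from sliding windows of phased SNPs. Includes a complete simulation
    stack: bivalent-only autotetraploid meiosis under the Haldane mapping
    function, random-mating drift of ancestral groups, nested association
    mapping (NAM) population construction, additive phenotype simulation, and
    a power-evaluation framework (permutation significance thresholds,
    linking-distance QTL intervals, detection power, false-positive rate,
    precision and peak accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    yaml
Config/testthat/edition: 3
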