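Package: zwmap
Title: Sex-Locus Mapping in Heterozygous F1 Populations by Bulked-Segregant
    SNP-Index Analysis, W-Region Depth Mapping and Pseudo-Testcross Linkage
Version: 0.1.0
Authors@R:
    person("zwmap", "developers", email = "zwmap@example.org", role = c("aut", "cre"))
Description: Tools for locating a female-specific (W-linked) sex locus in a
    dioecious outcrossing species from a single F1 cross between two
    heterozygous parents. Implements F1-adapted QTL-seq (parent-substituted
    references, parent-specific heterozygous site classification, bulk
    SNP-index and delta-SNP-index with sliding windows and simulation-based
    confidence limits), identification of female-specific genomic regions by
    uniqueness-aware read mapping to a combined dual-parent reference,
    pseudo-testcross RAD linkage mapping with scaffold splitting, repulsion
    phase correction and pseudo-molecule construction, genome-size estimation
    (k-mer and flow-cytometry formulas), SSR scanning, and in silico
    PCR/CAPS genotyping of sex-diagnostic markers. A synthetic-population
    module generates ZW/ZZ crosses with configurable heterozygosity, a
    female-specific W insertion and labile sex expression, providing ground
    truth for every analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
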