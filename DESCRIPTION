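Package: oryzaQC
Title: Diagnostic SNP Panel Selection and Validation for Rice Genebank
    Quality-Control Genotyping
Version: 0.1.0
Authors@R:
    person("Genebank", "Genomics Team", email = "genebank-qc@example.org",
           role = c("aut", "cre"))
Description: Tools to select and validate small panels of taxon-diagnostic
    biallelic SNP markers for quality-control genotyping of germplasm
    collections spanning four Oryza species and two O. sativa subspecies.
    Implements per-marker quality statistics (minor allele frequency,
    polymorphism information content, gene diversity, heterozygosity,
    missingness) and a quality-filter cascade; minor-allele concordance
    scoring of group-diagnostic markers with jointly-diagnostic marker
    pairs and greedy minimal-panel reduction; accession classification by
    expected haplotype; and a population-genetic validation battery:
    one-level AMOVA with PhiPT and permutation tests, pairwise PhiPT,
    principal component analysis, neighbor-joining trees with locus
    bootstrap, and DAPC-style selection of the number of clusters by BIC
    and silhouette. A fully seeded synthetic-collection generator with
    planted ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
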