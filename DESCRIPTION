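Package: nhxdiverge
Title: Divergence Analysis of Duplicated Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for studying functional divergence of small
    plant gene families such as the Na+/H+ exchanger (NHX) antiporters of
    Populus. Implements Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor
    correction, sliding-window selection scans and Ks-based duplication dating;
    protein characterization (pairwise identity, deduced ORF length, molecular
    weight, isoelectric point, Kyte-Doolittle transmembrane segmentation) and
    neighbor-joining subfamily assignment; IUPAC consensus scanning of
    promoters for cis-acting elements; Pearson-threshold co-expression
    networks with shared-hub detection and hypergeometric term enrichment;
    variant consequence annotation against gene models with
    transmembrane-overlap summaries; and seeded synthetic-data generators
    that emulate an eight-member gene family so every stage is testable
    end-to-end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
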