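Package: nomere
Title: Single-Cell NOMe-Seq Regulome Analysis with a Ground-Truth Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for single-cell nucleosome occupancy and
    methylome sequencing (NOMe-seq) combined with single-cell RNA-seq in
    early embryos. Calls nucleosome-depleted regions (NDRs) from pooled GCH
    methylation by sliding-window chi-square tests, quantifies WCG
    methylation and GCH accessibility over sites, regions, TSS windows and
    genic running-window profiles, links NDRs to candidate target genes by
    coverage-weighted Pearson correlation with BH false-discovery control,
    scores per-cell transcription-factor activity against a permutation
    background, reconstructs blastomere lineages from pairwise
    bin-methylation correlations, infers copy-number variation from
    expression profiles and from binned bisulfite read counts, and tests
    allele-specific methylation on 500-bp tiles with Fisher exact tests.
    A lineage-structured synthetic multiomics generator with a full
    ground-truth manifest makes every stage testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
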