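Package: diplomap
Title: Ancestry Diplotyping of Hybrid Crosses from Targeted-Capture Read Pileups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-locus ancestry diplotypes (BbHOM, HET, BvHOM) for a
    three-generation hybrid cross directly from raw per-position read-count
    matrices (PoPoolation2 sync dialect), without per-position genotype calls.
    Grandparental counts are turned into a significance-weighted polarized
    matrix; samples are scored and clustered in the two-taxon coordinate
    system; maximum-likelihood taxon haplotypes and per-sample diplotypes are
    coestimated under a Mendelian model with an enrichment-bias admixture
    coefficient, robust to overmerged (mis-mapped) reads. Downstream tools
    compute segregation-distortion chi-square statistics with dual
    significance thresholds, reduce linkage-map bins to single loci, scan the
    map for the sex-determining region via the sex-homozygote bias statistic,
    and infer heterogamety from cluster-sex statistics. A seeded simulator
    generates sync-format crosses with overmerging contamination, capture
    bias, and an optional XY/ZW sex locus. Writers for Lep-MAP3 posterior
    input are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
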