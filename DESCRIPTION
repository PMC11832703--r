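Package: pgsrank
Title: Curation, Annotation and Consensus Ranking of Polygenic Score Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating collections of polygenic score (PGS) scoring
    files, annotating their variants to nearest genes, and prioritizing
    variants that are consistently important across scores. Scoring files in
    the PGS Catalog distribution format are parsed, quality-controlled
    (standard rsID filtering, methodological classification, redundancy and
    limited-scope detection), and combined into a cross-score rank matrix in
    which a variant missing from a score receives the worst rank N. Six rank
    aggregation algorithms produce consensus rankings: Dowdall (mean
    reciprocal rank), Robust Rank Aggregation, the Stuart joint
    order-statistic method, and Borda minimum, geometric-mean and mean rank.
    Consensus rankings are benchmarked against a GWAS priority score built
    from external association data, and a synthetic-data generator with
    planted consensus variants supports end-to-end testing without any
    network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
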