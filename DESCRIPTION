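Package: genelit
Title: Literature-Wide Analysis of Early-Stage Research into Human Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds gene-highlight tables from publication records and
    gene-mention annotations, classifies gene ages (new, recent, old targets),
    and computes the temporal, contextual (journal, funder, organization),
    field (genome biology, GWAS), citation-impact, and concentration
    statistics of early-stage research into human protein-coding genes.
    Includes self-contained statistical primitives (exact 2x2 test,
    Bonferroni control, percentile bootstrap, rank correlation, within-cohort
    percentiles), a citation-graph disruption index, and a synthetic corpus
    generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    ape,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
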