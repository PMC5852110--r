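Package: t2bsgo
Title: Taxa-to-Brain-Substructure Association Through Shared Gene Ontology
    Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico pipeline that associates gut-microbiota taxa with
    human brain substructures through shared Gene Ontology (GO) annotations.
    A brain gene-by-sample count matrix is filtered and tested for
    per-substructure differential expression with a negative-binomial
    quasi-likelihood F-test; per-taxon protein homology hit tables are
    resolved to non-redundant human gene sets; both gene lists are enriched
    for GO terms by Fisher's exact test with Bonferroni control; the
    significant term sets are intersected into taxon-by-substructure
    association records; and the shared terms are summarised with
    Sorensen-Dice similarity matrices and grouped into a-posteriori GO slims
    by hierarchical clustering of shortest-path semantic distances. A
    seeded synthetic-data generator emulates every input (ontology,
    annotations, counts, homology hits) with planted associations so the
    whole pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
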