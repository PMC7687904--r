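Package: qtlannot
Title: Local Annotation of GWAS Variants and Genes with Quantitative Trait Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ingests heterogeneous QTL summary-statistics tables into a
    canonical store, computes linkage-disequilibrium aware significance and
    best-signal flags, classifies variant-gene pairs as cis or trans using
    topologically associating domain (TAD) boundaries, links records to GWAS
    Catalog associations, and serves mixed variant/gene queries with LD proxy
    expansion, filtering and haplotype-block aggregation. Includes pipeline
    stages for two explorative analyses (gene-to-best-eQTL distance
    distributions and cross-tissue eQTL sharing per LD block with
    hypergeometric gene-set enrichment) and a deterministic synthetic fixture
    generator emulating all input formats at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
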