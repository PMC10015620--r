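Package: poolgea
Title: Pool-Seq Genome-Environment Association Scans with Local Score
    Zone Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-environment association (GEA) analysis for pooled
    whole-genome sequencing of natural populations. Parses pooled VCFs into
    allele read count matrices, applies depth/missingness/biallelic filters,
    estimates the among-population covariance of scaled allele frequencies
    (Omega), and scans for SNP-environment associations with a conjugate
    Bayes factor on Omega-whitened frequencies together with the XtX spatial
    differentiation statistic. Per-SNP scores are aggregated into candidate
    regions with the Lindley local-score process, tested for overlap with
    the differentiation tail via circular permutations, and mapped to
    candidate genes from a GFF3 annotation. Includes plant-pollinator
    network indices (degree, partner diversity, d-index and related
    species-level measures), visitation BLUPs, Spearman pruning of
    ecological variables, and a synthetic-data generator with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    lme4,
    vegan,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
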