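Package: mircms
Title: Small RNA, Degradome, and Transcriptome Integration for Plant miRNA Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable re-implementation of a plant small-RNA analysis
    pipeline linking cytoplasmic male sterility (Ogura-CMS) to
    miRNA/target cascades in Brassica rapa: read cleaning and tag
    collapsing, miRBase-style known-miRNA identification and family
    expansion, hairpin folding with Mireap-style novel miRNA discovery,
    tag-count normalization (TPM/RPKM) and differential expression
    (Audic-Claverie and chi-squared tests with BH FDR), degradome
    (PARE) cleavage-site target validation with Allen-type
    complementarity scoring and t-plot categories, and joint
    miRNA-target expression clustering. Ships a deterministic
    synthetic-data generator with recorded ground truth so every stage
    is testable without the original sequencing runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
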