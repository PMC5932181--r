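Package: mirsnptools
Title: Integrative Prioritization of MicroRNA Binding-Site Variants in
    Autoimmune Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates per-tool predictions of microRNA binding-site
    disruption or creation by 3' UTR variants (miRSNPs) into a naive Bayes
    combined score, filters candidates against GWAS summary statistics with
    linkage-disequilibrium proxy expansion and a shared-disease rule,
    annotates survivors with eQTL evidence, and tests genotype-stratified
    Pearson correlation between miRNA and target mRNA expression.  Ships a
    transcription of a published candidate table as a plain-text fixture and
    a synthetic-data generator with a planted truth set so every stage and
    the end-to-end pipeline are testable without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
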