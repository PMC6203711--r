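Package: nashhcc
Title: Somatic Mutation and Expression Analysis for NASH-Related Liver Cancer Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paired tumor-normal somatic variant analysis for studies of
    steatohepatitis-driven hepatocellular carcinoma. Implements a six-stage
    statistical filter cascade for somatic single-nucleotide variants
    (allele-fraction gate, tumor-vs-normal Fisher test, high-quality
    coverage gate, sequencing-error binomial screen, base-quality Wilcoxon
    screen, repeat-alignment and read-end Fisher screens), a rule-based
    somatic indel filter with known-sites exclusion, consequence annotation
    on toy genomes, mutation recurrence and burden statistics,
    differential-expression calling on log2-ratio matrices, and
    hypergeometric pathway enrichment with Benjamini-Hochberg adjustment.
    A synthetic-data module generates paired pileups, expression matrices
    and gene-set collections with known ground truth so every stage's
    sensitivity and specificity are measurable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
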