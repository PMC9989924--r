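Package: coordscan
Title: Transcriptome Coordination Analysis for Genetically Diverse Samples
Version: 0.1.0
Authors@R:
    person("Coordscan", "Developers", email = "coordscan@example.org",
           role = c("aut", "cre"))
Description: Identifies genes coordinated with a pathway of interest by
    correlating whole-transcriptome correlation profiles across genetically
    diverse individuals. Provides per-gene correlation profiles, a gene-pair
    coordination statistic with analytic and permutation significance,
    panel-based candidate scanning, hypergeometric gene-set enrichment with
    Benjamini-Hochberg FDR, TSS-relative promoter consensus scanning with
    IUPAC-aware edit distance, and a seeded latent-factor expression
    simulator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
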