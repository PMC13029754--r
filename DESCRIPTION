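Package: dualnod
Title: Dual-Transcriptome Analysis of Legume-Rhizobium Nodules
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for paired host/symbiont ("dual") RNA-seq of
    nitrogen-fixing root nodules, from gene-level count matrices through
    low-expression filtering, trimmed-mean-of-M-values (TMM) normalization,
    negative-binomial exact-test differential expression with
    Benjamini-Hochberg FDR, gene-set over-representation, single-sample
    module z-scores with a cross-partner Pearson coupling test, and
    phenotype/RT-qPCR statistics (Welch t, acetylene-reduction rates,
    2^-ddCt). Includes a calibrated synthetic-data generator that emulates
    a two-treatment, three-replicate nodule experiment with host-dominant
    libraries, planted fold changes, and a latent factor coupling a host
    supply module to a symbiont nitrogen-fixation module.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
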