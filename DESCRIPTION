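Package: riboshift
Title: Translational Efficiency and RNA Methylation Analysis for Paired
    RNA-Seq/Ribo-Seq and Bisulfite Sequencing Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential RNA abundance and ribosome occupancy from paired
    RNA-seq and Ribo-seq count matrices using per-transcript negative
    binomial generalized linear models, classification of transcripts with
    enhanced translational efficiency (unchanged RNA abundance, increased
    ribosome occupancy), and an assay-by-condition interaction test for
    changes in translational efficiency. Also provides cytosine methylation
    quantification from bisulfite RNA sequencing pileups with conversion
    efficiency correction, high-methylation site calling, an empirical Bayes
    moderated t-test for differential site methylation, amplicon bisulfite
    clone analysis, and hypergeometric gene-set over-representation.
    Includes a synthetic data generator with ground-truth tables for
    calibration and recovery testing, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
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
    limma,
    DESeq2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
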