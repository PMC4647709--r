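Package: misasm
Title: Reference- and Read-Based Detection of Mis-Assemblies in Draft Genome
    Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies mis-assemblies (misjoins, erroneous insertions and
    deletions) in draft assembly scaffolds by combining scaffold-to-reference
    alignment differences with multi-feature paired-end read evidence:
    per-base pileup disagreements, windowed coverage anomalies (including a
    single-cell mode for highly uneven depth), multi-align ratios, discordant
    read-pair ratios, and insert-size tests on pairs spanning breakpoint
    regions. Differences supported by clean read evidence are reported as
    correct assemblies reflecting structural variation between the target
    and reference genomes rather than as errors. Validated errors are
    corrected (scaffold splitting and end trimming) and assembly statistics
    are reported before and after correction. Includes a fully seeded
    synthetic-scenario generator (genome, mis-assembled scaffolds,
    SV-mutated reference, paired-end reads with Gaussian insert sizes) and
    naive long-sequence and short-read aligners so the whole pipeline runs
    hermetically at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown,
    optparse
Config/testthat/edition: 3
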