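Package: strharvest
Title: Short Tandem Repeat Instability from Short-Read Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and quantifies DNA-repeat instability from short-read
    sequencing alignments. Extracts in-repeat reads (IRRs) for any 2-6 bp
    motif and assigns them to catalog loci via mate positions, measures
    repeat allele lengths from spanning reads, filters PCR-stutter
    artifacts using the within-read base-quality signature of polyclonal
    sequencing clusters, estimates allele-specific germline expansion and
    contraction rates from alleles shared identical-by-descent, and builds
    somatic-expansion phenotypes (per-allele expansion fractions, age
    trends, IRR-based long-allele length estimates, fragment-based
    expansion scores and group-calibrated phenotypes). A seeded synthetic
    read generator emits SAM alignments with ground-truth tables so that
    every stage is testable without access-restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Rsamtools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
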