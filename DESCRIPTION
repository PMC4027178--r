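Package: telolen
Title: Telomere Length Estimation from Shotgun Sequencing Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates mean telomere length in kilobases from whole-genome or
    exome shotgun sequencing data. Reads are classified as telomeric when they
    carry at least k copies of the telomere repeat hexamer (TTAGGG or its
    reverse complement CCCTAA); the telomeric read count is normalized by the
    abundance of reads whose GC composition matches the telomeric value (48-52%)
    and converted to a physical length using the cumulative reference length at
    that GC composition divided by the number of telomere ends. Works per read
    group on BAM/SAM (including unmapped reads) or FASTQ input. Includes a
    reference GC profiler, a paired-end read simulator with telomere-bearing
    synthetic genomes for coverage-titration validation, and replicate
    statistics (coefficient of variation, variance F-test, bootstrap comparison
    of correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rsamtools,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
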