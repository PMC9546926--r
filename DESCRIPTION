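Package: gvmine
Title: Mining Giant Virus Sequences from Soil Metagenome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects Nucleocytoviricota (giant virus) scaffolds in soil
    metagenome assemblies from per-scaffold counts of viral marker-profile and
    cellular protein matches, using a calibrated linear decision boundary with
    a eukaryotic false-positive constraint. Includes assembly chimera
    assessment against reference genomes, marker-gene extraction with a
    second-match first-quartile paralog filter, coverage-based relative
    abundance and virus-eukaryote co-occurrence statistics, and a synthetic
    control-database generator (simulated metagenomic contigs, class-conditional
    hit counts, planted chimeras and abundance matrices) so the whole analysis
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    methods,
    Rsamtools,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
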