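Package: qpcrcnv
Title: Copy-Number Genotyping from Comparative-CT qPCR with Growth
    Association and Ferritin Sequence Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates diploid gene copy number from real-time quantitative
    PCR threshold-cycle (Ct) tables by the comparative-CT method with a
    single-copy control locus, calibrates amplification efficiency from
    genomic-DNA dilution series, and converts fractional estimates into
    integer copy-number genotypes using cutoff-based calling with an
    explicit no-call zone.  Summarizes genotype frequencies per population
    and tests copy-number/growth-trait associations with Student and Welch
    two-sample t-tests, from raw phenotypes or from published group
    summaries.  Annotates ferritin-style transcripts: open reading frame
    and UTR partition, polyadenylation signals, protein mass and
    isoelectric point, iron-responsive element (IRE) stem-loops by
    consensus matching, and exon-intron structure from spliced
    cDNA-to-genomic mapping constrained to canonical GT/AG splice sites.
    A seeded synthetic-data generator emulates populations, Ct tables,
    dilution series and phenotypes with known ground truth so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
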