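Package: racescreen
Title: Promoter Activity Screening from 5' RACE-Seq of Randomized Promoter Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of massively parallel promoter-activity
    screens read out by 5' RACE sequencing. The package simulates in vitro
    transcription from T7- or SP6-type promoter templates with a randomized
    initially transcribed region (+2..+16), including polymerase slippage at
    G-triplet starts, non-templated C addition by reverse transcriptase,
    poly(A) tailing, PCR duplication and sequencing error; processes paired
    reads (structural 5' end filter, 15mer-UMI deduplication, contaminant and
    constant-sequence filters); computes background-normalized motif
    abundances, position-wise nucleotide composition, dinucleotide group
    summaries, extra-G fractions, motif ranks and activity fold-ranges; and
    scores or optimizes initially transcribed regions for promoter design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    stringi,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
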