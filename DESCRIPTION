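Package: splicemaps
Title: Motif RNA Maps Around Regulated Cassette Exons with Post-Hoc FDP Bounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds positional RNA maps of RNA-binding-protein motifs around
    differentially spliced cassette exons. Reads rMATS-format differential
    splicing tables, applies read-support/effect-size/FDR significance filters
    and background-exon selection, extracts strand-aware 300-nt regions
    flanking each cassette exon from a genome FASTA, scans degenerate IUPAC
    motifs in 50-nt sliding windows, and compares per-window motif counts
    between regulated and background exons with the Wilcoxon rank-sum test.
    Extends the classical minimum-p-value RNA-map summary with post-hoc
    inference: simultaneous Simes-template upper bounds on the false discovery
    proportion (FDP) over every contiguous window interval, so significantly
    enriched intervals can be selected at a user-chosen FDP threshold after
    seeing the data. Also provides event-set overlap (hypergeometric),
    delta-PSI direction concordance, and two-proportion chi-square statistics,
    plus a seeded synthetic-data generator with planted motifs and full ground
    truth for pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
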