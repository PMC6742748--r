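Package: tuarch
Title: Transcription Unit Architecture from dRNA-Seq and Term-Seq End Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the transcription unit (TU) architecture of a
    bacterial genome from strand-specific sequencing end profiles. Calls
    transcription start sites (TSSs) from differential RNA-Seq (TAP+/TAP-)
    5'-end counts, calls transcript 3'-end positions (TEPs) from replicated
    Term-Seq profiles using a leave-one-out modified z-score, classifies both
    site types against a gene annotation, assembles and clusters TUs under an
    intergenic-distance rule, and derives regulatory-feature statistics
    (5'-UTR lengths and leaderless transcripts, start-codon usage, promoter
    and terminator sequence windows, spacer lengths, nucleotide enrichment,
    RPKM and translation efficiency). Includes a synthetic-data generator
    that emulates the statistical structure of all six library types so the
    whole pipeline can be exercised and benchmarked against a known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
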