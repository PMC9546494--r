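Package: rtdforge
Title: Reference Transcript Dataset Construction from Long-Read and
    Short-Read RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a filtered reference transcript dataset (RTD) from
    aligned full-length long cDNA reads and short-read splice-junction
    evidence. Implements high-confidence splice-junction selection
    (canonical motifs, near-junction mismatch windows, Hamming-distance
    template-switching detection), binomial-enrichment and fixed-window
    calling of transcription start and end sites with an internal-priming
    filter, 1-bp-resolution read collapsing, end-wobble transcript
    merging, rule-based integration of long- and short-read
    transcriptomes, motif-density validation of called ends, chimera and
    splicing-ratio benchmarking, and a fully seeded simulator of genomes,
    long-read alignments, junction tables and abundance matrices for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
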