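Package: LDPCStorage
Title: DNA-Based Data Storage with an Inter-Oligo LDPC Code and
    Sequence-Analysis-Aided Soft Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encoder, channel simulator and decoder for archival data
    storage in synthetic DNA. Binary files are randomized, protected by a
    CRC-32 checksum, partitioned across oligonucleotides and protected by
    a single high-rate low-density parity-check (LDPC) code applied in the
    inter-oligo direction, with each oligo's address protected by an (8,4)
    Reed-Solomon code over GF(16). The decoder clusters variable-length
    sequencing reads by their Reed-Solomon-decoded index, evicts abnormal
    reads by edit distance, co-registers variable-length clusters with a
    center-star multiple alignment, converts quality-score-gated base
    votes into log-likelihood ratios and recovers the stored file by
    iterative belief-propagation re-decoding. A configurable
    substitution/insertion/deletion channel with Phred quality emission
    reproduces merged Illumina-style read corpora for end-to-end
    evaluation.
License: MIT
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'LDPCStorage-package.R'
    'RcppExports.R'
    'bits.R'
    'channel.R'
    'crc32.R'
    'decode.R'
    'ldpc.R'
    'encode.R'
    'eval.R'
    'gf16.R'
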