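Package: dnafountain
Title: Near-Optimal Rateless Erasure Codes for DNA Data Storage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Encode arbitrary binary data into DNA sequences with rateless
    erasure (fountain) codes and decode the original data back from any
    sufficiently large subset of sequences. Implements the LT code with
    Ideal and Robust Soliton degree distributions, Online codes with
    auxiliary-block outer encoding, and non-systematic Raptor codes with an
    LDPC/Half precode and the fixed degree table; GF(2) Gaussian-elimination,
    belief-propagation and structure-only pseudo decoders; a configurable
    packet wire format with CRC-8, CRC-32 and Reed-Solomon integrity checks;
    a binary-to-nucleotide converter with FASTA input and output; a DNA
    stability rule engine (GC content, homopolymers, micro-satellites) that
    scores candidate sequences; and driver routines for seed-space sweeps,
    error-bounded packet preselection and erasure-channel simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
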