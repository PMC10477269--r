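Package: frqiseq
Title: Quantum-Circuit Pairwise Nucleotide Sequence Similarity via FRQI
    Encoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes pairs of equal-length nucleotide sequences as
    angle-parameterized quantum states using the flexible representation of
    quantum images (FRQI), builds the strip-qubit parallel-comparison circuit,
    and estimates the probability P1 of measuring 1 on the strip qubit by a
    closed form, by exact statevector simulation, or by seeded finite-shot
    sampling. The similarity score is sim = 1 - 2*P1. Includes multi-controlled
    rotation decomposition to single-qubit U and CNOT basis gates, circuit
    depth and gate-count metrics, OpenQASM 2.0 export, FASTA input, a mutated
    fixture-pair generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
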