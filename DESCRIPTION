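Package: pnpminer
Title: Motif-Based Mining and Annotation of Neuropeptide Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovery and annotation of proneuropeptide (pNP) candidates in
    translated transcriptomes. Implements signal-peptide gating followed by a
    regular-expression screen for multicopy peptide precursors (repeated
    amidation or dibasic cleavage sites), greedy redundancy reduction, a
    two-pass (relaxed then stringent) local-alignment similarity search with
    connected-component clustering, a prohormone-convertase processing model
    (dibasic and monobasic cleavage, C-terminal amidation, N-terminal
    pyroglutamate), matching of observed mass-spectrometric peptide
    identifications to predicted precursor products, and exon-intron
    structure comparison (intron positions in protein coordinates and intron
    phases) as homology evidence. A deterministic synthetic-data generator
    emulates secreted multicopy precursors, Cys-domain precursors, decoy
    sequences, gene models with planted introns, and MS identification
    lists, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
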