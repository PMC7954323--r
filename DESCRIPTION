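Package: mxestruct
Title: Structural and Functional Impact of Mutually Exclusive Exon Switching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects homologous mutually exclusive exon (MXE) events,
    cassette exons and microexons from gene annotations, maps the variable
    residues of MXE isoform pairs onto protein structures, and quantifies
    their solvent exposure, physicochemical change (McLachlan score), 3D
    clustering and proximity to functional sites and cancer mutation
    residues against randomisation null models. Ships a synthetic-data
    generator that plants events, toy structures, alignments and mutation
    sets with known ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
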