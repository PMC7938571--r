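Package: circribo
Title: Detection, Annotation and Evidence Classification of Ribosome-Associated Circular RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for finding translation evidence on circular RNAs
    (circRNAs). Builds a back-splice junction (BSJ) pseudo-reference from
    full-length circRNA sequences, calls ribosome-associated circRNAs from
    junction-spanning ribosome-profiling footprints, predicts circRNA-derived
    open reading frames (cORFs) under rolling-circle translation on a
    concatenated template, annotates translation-supporting cis-elements
    (IRES hits, m6A RAC sites, per-base conservation), infers cross-species
    conserved translatable circRNAs by reciprocal best hits between BSJ flank
    sequences, and classifies proteomic junction-spanning peptide evidence.
    Includes a deterministic synthetic-data generator so every stage is
    testable without downloads, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
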