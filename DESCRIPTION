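Package: caspomap
Title: Casposase Integration-Site Mapping from Junction Reads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps in vitro casposase integration sites on a circular target
    plasmid from stranded junction sequencing reads. Reads are collapsed to
    unique sequences with abundances, filtered for the casposon-end junction
    signature, clipped to their target-derived suffix, and aligned without
    gaps to both strands of the circular reference. Strand-paired insertion
    sites yield the target-site-duplication (TSD) length, site frequencies,
    and abundance-weighted nucleotide frequency matrices of the target motif.
    Includes a synthetic junction-read simulator with ground truth, and
    closed-form models of denaturing-gel product lengths, plasmid topology
    outcomes, and oligonucleotide/protein complex masses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
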