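Package: funsite
Title: Structure-Based Inference of Protein Functional Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting enzymatic functional sites on protein
    structures by combining independent lines of structural and evolutionary
    evidence: grid-based cavity detection and ranking, backbone "nest" motif
    detection from phi/psi geometry, three-dimensional matching of catalytic
    residue templates (e.g. glycoside-hydrolase acid triads), solvent
    accessibility and exposed-aromatic analysis, sequence-conservation mapping
    from a multiple sequence alignment onto the structure, and
    sequence-independent superposition of internal structural repeats.  Also
    provides Poisson-corrected distance phylogenetics (neighbor joining with
    bootstrap supports) and a synthetic-data generator that plants catalytic
    constellations, cavities of known volume, nest backbones and alignments
    evolved along known trees, so that every stage of the pipeline can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d,
    phangorn,
    optparse
Config/testthat/edition: 3
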