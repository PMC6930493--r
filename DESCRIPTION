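Package: GAGdigest
Title: In-Silico Enzymatic Sequencing of Heparin and LMWH Oligosaccharides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for structure elucidation of heparin and low-molecular-weight
    heparin (LMWH) oligosaccharides by combined heparin lyase and heparanase
    digestion read out by negative-mode ion-pair mass spectrometry. Provides a
    residue-level grammar and composition-code nomenclature for
    glycosaminoglycan (GAG) sequences, exact monoisotopic mass and
    dibutylamine-adduct m/z arithmetic, rule-based simulation of heparinase
    I/II/III eliminative cleavage and heparanase hydrolysis with
    sulfation-context susceptibility rules, Domon-Costello CID fragment
    enumeration and MS/MS peak annotation, constraint-based inference of
    candidate sequences from digestion evidence, and a synthetic heparin-like
    chain generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'constants.R'
    'parse.R'
    'composition.R'
    'enumerate.R'
    'mass.R'
    'digest-lyase.R'
    'digest-heparanase.R'
    'fragments.R'
    'annotate.R'
    'infer.R'
    'paper-tables.R'
    'simulate.R'
    'io.R'
    'cli.R'
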