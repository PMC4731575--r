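Package: h1ptm
Title: Discovery and Mapping of Post-Translational Modifications in Linker Histones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bottom-up proteomics toolkit for discovering and mapping
    post-translational modifications (PTMs) on lysine-rich proteins such as
    plant linker histones (H1). Provides exact monoisotopic and average mass
    arithmetic over CHNOPS compositions, in-silico digestion with trypsin,
    Arg-C, thermolysin and pepsin, theoretical HCD b/y/internal fragment
    generation for modified peptides, MGF spectrum input/output and
    tolerance-based peak annotation, open (delta-mass) modification search
    with fragment-ladder site localization, low-m/z-preferred modification
    mass refinement, elemental composition enumeration with chemical
    plausibility filters, intact-mass variant assignment, a ground-truthed
    synthetic spectrum generator, and per-residue modification map reporting
    with hot-spot and S/TPxK motif detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
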