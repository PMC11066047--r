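Package: XLinkMS
Title: Cross-Linking Mass Spectrometry Validation, Docking Restraints, and
    Companion Quantification Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for processing cross-linking mass spectrometry (XL-MS)
    residue-pair identification tables and validating them against
    three-dimensional structures: canonicalization, FDR filtering and
    deduplication of lysine-lysine connections; mapping of cross-links onto
    multi-chain PDB/mmCIF structures with homo-oligomer ambiguity resolution
    and Calpha-Calpha distance restraint checking (35 Angstrom DSBSO
    convention); export of unambiguous distance restraints for integrative
    docking and cross-link-based ranking of candidate models; construction of
    protein-protein interaction networks from inter-protein links; SILAC
    heavy/light enrichment statistics with significance tiers and label-swap
    concordance; and fluorescence image quantification (background
    subtraction, Otsu masks, Manders co-localization, line profiles,
    membrane/cytosol ratios). A synthetic-data module generates every input
    class with planted ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    Biostrings,
    bio3d,
    igraph,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
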