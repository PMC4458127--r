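Package: mpRepair
Title: Misassembly Detection and Correction in Draft Assemblies Using
    Mate-Pair Insert Sizes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects and excises large-scale misassemblies (scaffolding
    errors, large indels) in draft de novo assemblies using a mate-pair
    library aligned back to the assembly. Insert sizes of correctly
    oriented intra-contig pairs are modelled as a two-component mixture
    (a normal null component with robustly estimated parameters, and a
    uniform anomaly component over the contig). A per-position assembly
    support score is computed from the posterior null probabilities of
    pairs spanning each position, standardised per contig, and contigs
    are broken and trimmed where support falls far below the contig
    mean. Includes a mate-pair library simulator with engineered
    misassemblies and machine-readable truth, plus ROC-style evaluation
    of calls against truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
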