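Package: bamcollate
Title: Bounded-Memory Read-Name Collation, Duplicate Marking and FastQ
    Conversion for Alignment Files
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Collates alignments in coordinate-sorted SAM/BAM files by read
    name within a fixed memory budget, using a collisionless hash table
    backed by a ring buffer, a two-ended overflow list, name-sorted
    temporary runs and an external multiway merge. On top of the collation
    engine the package provides conversion of alignment files to FastQ
    (mate-resolved paired output plus orphan and single-end streams, with
    restoration of the original sequencing orientation) and duplicate
    marking by unclipped 5' mapping coordinate with a hybrid
    in-memory/external spill strategy. A paired-end alignment simulator
    with planted PCR-duplicate clusters, orphans, split pairs and
    single-end reads supplies ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
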