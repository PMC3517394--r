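Package: pacsac
Title: Parcel-Level Built-Environment Indices over Adjacency-Community Moving Windows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for summarizing parcel-level systematic social observation
    of the residential built environment into neighborhood indices anchored to
    census blocks. Implements a validated variable registry partitioned into
    built-environment domains, queen-contiguity adjacency over block polygons
    with a snap tolerance, primary and secondary adjacency community (PAC/SAC)
    moving windows, owner-occupancy classification by situs/owner address
    matching, point-in-polygon crime aggregation by offense category, seven
    block/PAC/SAC-level indices with correlation matrices, one-way intraclass
    correlation for inter-rater reliability, and a seeded synthetic city
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
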