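Package: ligninsmith
Title: Sequence-Controlled Generation of Lignin Macromolecule Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates chemically valid two-dimensional structures of milled
    wood lignin by sequence-controlled polymer growth. From a syringyl/guaiacyl
    (S/G) ratio, target inter-unit bond frequencies, and a degree of
    polymerization, the package enumerates unique monomer sequences, assigns
    the six major lignin linkages (beta-O-4, resinol, phenylcoumaran, biphenyl,
    dibenzodioxocin, diaryl ether) under literature coupling rules, assembles
    monomer-level molecular graphs, encodes them as adjacency/connectivity
    matrices, expands them to atom-level molecules with canonical SMILES and
    MOL output, and validates per-structure linkage and functional-group
    compositions against experimental reference ranges for spruce and birch
    milled wood lignin.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
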