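Package: tabscount
Title: Torsion Angular Bin Strings and Exact Conformational State Counting
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discretizes the rotatable-bond torsions of a molecule into
    angular bins, encodes each conformer as a torsion angular bin string
    (TABS), canonicalizes the strings under the molecule's topological
    symmetry group, and counts the number of distinct conformational
    states (nTABS) exactly via Burnside's lemma in O(|G| N) time.  Also
    provides a confusion-matrix framework (PPV/NPV, threshold sweeps,
    flexibility categories) for comparing the TABS same/different
    labeling of conformer pairs against continuous similarity metrics
    such as heavy-atom RMSD or shape Tanimoto, plus synthetic-system
    generators so every component is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
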