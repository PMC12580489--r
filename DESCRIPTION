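Package: dmaq2
Title: Aromaticity Descriptors from Distributed Multipole Quadrupoles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes aromaticity descriptors for ring molecules from
    distributed multipole analysis (DMA) quadrupole (Q2) tensors: parsing of
    GDMA punch-style site multipoles, exact rank-2 moment translation and
    rotation, six Q2-based descriptors with benzene normalization, an
    out-of-plane scan locating the maximizing evaluation height, adiabatic
    ionization potential / electron affinity and conceptual-DFT reactivity
    indices, squared-correlation screening against reactivity and literature
    aromaticity indices, and a chemometric stage (z-score standardization,
    principal component analysis, Ward-criterion hierarchical clustering).
    Synthetic multipole, energy and descriptor generators with exact
    point-charge oracles allow the whole workflow to run without any
    quantum-chemistry software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
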