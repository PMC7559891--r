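Package: scaffopt
Title: Mechanobiology-Based Optimization of Spherical-Pore Bone Scaffolds
Version: 0.1.0
Authors@R:
    person("scaffopt", "developers", email = "scaffopt@example.org",
           role = c("aut", "cre"))
Description: Parametric design and mechanobiological evaluation of regular bone
    tissue-engineering scaffolds built from cubic unit cells with a spherical
    pore and three orthogonal cylindrical interconnections. The scaffold and
    the granulation tissue filling its pores are modeled as biphasic
    poroelastic (Biot) materials on a voxel hexahedral mesh; the mechanical
    stimulus acting on the pore-filling tissue is scored with the Prendergast
    mechano-regulation model (octahedral shear strain plus interstitial fluid
    velocity) and the percentage of scaffold volume predicted to become mature
    bone (BO%) is maximized over the pore and interconnection diameters under
    geometric coherence constraints, for compression or shear loading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
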