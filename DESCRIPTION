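Package: channelCoupling
Title: Mutant-Cycle Coupling and Pore Geometry Analysis for Pentameric
    Ligand-Gated Ion Channels
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of two-electrode voltage-clamp
    dose-response data and channel structure for pentameric ligand-gated
    ion channels. Fits the variable-slope Hill model to per-oocyte
    concentration-response curves and aggregates per-construct summaries;
    computes fold changes, generalized mutant-cycle interaction factors
    (Omega), coupling free energies (Delta-Delta-G = RT ln Omega at 298 K)
    with propagated uncertainty; provides one-way ANOVA and Dunnett
    many-to-one comparisons against wild type computed from replicates or
    published summary triples; and implements the geometric measurements
    behind gating models: pore-axis estimation, radial pore-proximal /
    pore-distal classification of residues, interatomic hydrogen-bond
    distances, and a trans-pore CA-CA collapse metric. A seeded
    synthetic-data module emulates oocyte recordings and C5-symmetric
    pentamer coordinates so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
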