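Package: saxsens
Title: Ensemble-Based Small-Angle Scattering Analysis of Metal-Dependent
    Protein Oligomerisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise conformational and oligomeric equilibria
    of multi-domain proteins from small-angle X-ray scattering (SAXS) and
    structural models.  Provides coordinate and profile input/output with
    symmetry expansion of crystallographic assemblies, a bead-level
    synthetic conformer generator for two-domain monomers with disordered
    tails and C2-symmetric tetramers, Debye-equation forward scattering,
    primary SAXS reduction (Guinier, Kratky, regularised p(r) inversion,
    molecular-weight estimation, SEC-SAXS frame analysis), genetic-algorithm
    sub-ensemble optimisation against experimental curves, conformational
    state classification with population estimates, metal coordination-site
    detection and geometry classification, interface burial and hydrogen
    bonding, and convex-hull hydrodynamic radii with Stokes-Einstein
    conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
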