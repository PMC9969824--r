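Package: lipidvoro
Title: Voronoi-Based Analysis of Lipid Bilayer Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Per-lipid analysis of molecular dynamics simulations of flat
    lipid bilayers. Assigns lipids to leaflets (orientation-based, or
    position-based via a polynomial-regression midsurface), builds periodic
    two-dimensional Delaunay triangulations and Voronoi diagrams per leaflet
    with insertion of non-lipid (e.g. protein) atoms as extra generators, and
    derives per-lipid area per lipid (APL), local membrane thickness and
    neighbourhood profiles. Reads GROMACS-style inputs (PDB, NDX, XTC, TRR),
    streams trajectories frame by frame, synchronizes and compares multiple
    simulations, renders Voronoi maps and time-series plots, and exports
    results as XVG, TXT and XML. Includes a deterministic synthetic-bilayer
    generator so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    optparse,
    bio3d,
    png,
    xml2,
    stats,
    tools,
    utils
Suggests:
    deldir,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
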