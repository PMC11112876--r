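Package: hexchannel
Title: Geometry, Hydration and Per-Protomer Statistics for Hexameric
    Channel Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of multi-model PDB trajectories of hexameric
    membrane channels (connexin-style hemichannels): salt-bridge
    occupancy from terminal side-chain moiety centers of mass,
    transmembrane-domain representative-residue distances and
    inclination angles from total-least-squares helix axes, hydration
    counts of the intracellular pocket, Kabsch superposition RMSD and
    per-residue RMSF, and per-protomer nonparametric comparisons
    (Kruskal-Wallis). Includes a synthetic hexamer generator that
    plants salt bridges, helix tilts and pocket waters with a
    ground-truth manifest for validation, and a reproducible pipeline
    that writes tidy metric tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
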