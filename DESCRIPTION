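Package: poregate
Title: Permeability Kinetics, Pore Profiling and Gate Conformation Analysis
    for Aquaporin Channels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the quantitative analysis of pH-gated glycerol and water
    transport through aquaglyceroporin channels. Forward-simulates and fits
    vesicle and cell volume dynamics under osmotic shock to estimate water (Pf)
    and glycerol (Pgly) permeability coefficients; characterizes their pH
    dependence (Hill titration) and temperature dependence (Arrhenius
    activation energy); computes largest-inscribed-sphere pore radius profiles
    of channel structures in PDB format with region-wise constriction minima;
    and reduces gate-region trajectory ensembles to principal components with
    sieved k-means conformational clustering, per-condition population maps and
    representative structures. Seeded synthetic generators emulate every input
    class so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    bio3d,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
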