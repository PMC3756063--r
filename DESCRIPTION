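Package: revfiber
Title: Quantification of Dystrophin Revertant Fibers in Muscle Sections
Version: 0.1.0
Authors@R: person("Revfiber", "Developers", role = c("aut", "cre"),
    email = "maintainers@revfiber.dev")
Description: Tools to quantify dystrophin-positive ("revertant") fibers in
    transverse muscle sections of dystrophic animals: per-area fiber
    density, adjacency-based cluster detection, graph-separation isolated
    fibers, cluster size classes, and repeated-measures mixed-effects
    contrasts across muscles and age groups.  Includes a stochastic
    clonal-expansion simulator that generates pseudo-3D dystrophic muscle
    cohorts (founder reversion, cycle-wise expansion into adjacent fibers,
    de-novo reversion, longitudinal fiber extents and serial sectioning)
    so the full pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    lme4,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
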