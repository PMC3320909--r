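Package: usrsim
Title: Spatial Kinetic Monte Carlo Simulation of Prebiotic Polymer Evolution
    under Hydration-Dehydration Cycling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A spatially explicit hybrid kinetic Monte Carlo simulator of
    informational-polymer populations on a periodic surface lattice driven by
    hydration-dehydration cycles. Polymers of fixed length nucleate by
    spontaneous assembly and copy themselves by sequence-independent
    (universal) template-directed replication during the dry phase of each
    cycle; during the wet phase they hydrolyse back into monomers, hop between
    lattice sites, and -- for functional synthetase sequences -- convert a
    proto-monomer resource into usable monomers. Monomer diffusion is
    coarse-grained as mass-action transport; monomer mass is strictly
    conserved and recycled. The package tracks every sequence lineage,
    computes per-cycle system metrics (total population, extant species,
    species lifetime and population size, sequence exploration rate, average
    local Shannon diversity), provides parameter-sweep and
    functional-selection experiment drivers, a fully stochastic reference
    implementation for validating the hybrid engine, checkpointing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    Matrix
Config/testthat/edition: 3
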