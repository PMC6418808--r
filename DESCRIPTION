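Package: dpdgel
Title: Dissipative Particle Dynamics of Nano-Silica Aggregation in
    PVA/PAM Blended Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Coarse-grained dissipative particle dynamics (DPD)
    simulation and analysis of nano-silica dispersion in polyvinyl
    alcohol (PVA) / polyacrylamide (PAM) blended hydrogels.  Maps
    Flory-Huggins interaction parameters to DPD repulsion parameters,
    builds bead-spring initial configurations, integrates the
    equations of motion with a momentum-conserving pairwise thermostat
    under periodic or Lees-Edwards sheared boundaries, and computes
    the aggregation observables: slab-resolved relative concentration
    profiles, planar concentration maps, mean squared displacement and
    Einstein diffusion coefficients, and distance-based cluster
    statistics.  Ships the study designs (nano-silica content, polymer
    ratio, temperature and shear-rate sweeps) as runnable scenario
    presets at full and reduced scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
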