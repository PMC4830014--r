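Package: tiltsplay
Title: Membrane Elastic Moduli from Lipid Tilt and Splay Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts the lipid tilt modulus and the bending rigidity of
    lipid assemblies of arbitrary shape and composition from molecular
    dynamics trajectories, following the tilt/splay fluctuation approach
    rooted in Helfrich continuum theory. Provides periodic-boundary
    trajectory extension and wrapping, density-map based rigid trajectory
    alignment, extraction of the water-lipid interface and its normal
    vector field, per-lipid tilt and pairwise splay sampling, and
    potential-of-mean-force fitting of the resulting distributions,
    together with a calibrated synthetic-data generator for validation.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
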