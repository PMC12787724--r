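Package: netrod
Title: Langevin Dynamics and Diffusion Analysis of Nanorods in Cross-Linked Polymer Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coarse-grained bead-spring simulation of thin and thick nanorods
    diffusing in a cross-linked cubic polymer network, together with the full
    translational and rotational diffusion analysis stack: mean-square
    displacement (total and decomposed parallel/perpendicular to the rod major
    axis), the anisotropy parameter A(t), local anomalous-diffusion exponents,
    diffusion-coefficient and power-law scaling fits, non-Gaussian parameters,
    mean-square angular displacement and rotational diffusion coefficients.
    Includes a deterministic network/rod system builder, a Langevin integrator
    (Gronbech-Jensen-Farago scheme) with truncated-shifted Lennard-Jones,
    harmonic bond/angle and junction-tether potentials, an ideal rigid-rod
    Brownian trajectory generator for analysis validation, and readers/writers
    for extended XYZ, LAMMPS data and LAMMPS dump formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
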