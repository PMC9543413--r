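Package: fearcf
Title: Adaptive Flat-Histogram Free Energies from Reaction Coordinate Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multidimensional free-energy surfaces by adaptive
    flat-histogram biasing along reaction coordinates defined as directed
    graphs over atomic coordinates (distances, angles and dihedrals built
    from atoms, centers of mass, vectors and plane normals). Biasing forces
    are propagated from reaction-coordinate space to atoms by the chain rule
    along graph paths; per-iteration replica histograms are combined with
    the weighted histogram analysis method (WHAM) and the bias is updated to
    the negative of the running free-energy estimate until sampling is flat.
    Ships a self-contained toy molecular dynamics engine (flexible
    TIP3P-style water dimer and analytic test potentials) with
    velocity-Verlet integration and Langevin, velocity-scaling and
    Nose-Hoover thermostats, spline-interpolated bias gradients, and
    trajectory analyses: free-energy minima, Boltzmann-averaged projections,
    dipole-dipole autocorrelation with exponential relaxation fits, and
    geometric classification of water-dimer hydrogen-bond configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
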