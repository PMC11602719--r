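Package: toruspin
Title: Toroidal Attractor Analysis of Grid-Cell Populations with Landmark Pinning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing grid-cell population activity on a
    twisted-torus neural sheet during one-dimensional virtual-reality navigation.
    Includes a synthetic-session generator (diffusive path integration plus weak
    landmark pinning of the attractor bump, Poisson spiking, licking behaviour),
    spatial rate maps and spectrograms, spectral grid-cell classification and module
    clustering, Fourier phase extraction and sheet sorting, bump centre-of-mass
    tracking with unwrapping, trajectory geometry (anisometry, geodesic curvature,
    angular diffusion, pinning dispersion), a fixed landmark-pinning dynamical model
    with held-out prediction and a Hebbian variant, circular-linear position decoding,
    a plastic behavioural-timescale downstream decoder, and behavioural metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
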