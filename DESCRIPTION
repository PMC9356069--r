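Package: fnsampler
Title: Fractional Neural Sampling with Levy-Driven Dynamics and Spiking Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for sampling-based probabilistic computation driven by Levy
    (alpha-stable) motion. Provides symmetric alpha-stable densities, variate
    generation and maximum-likelihood fitting; numerical Riesz fractional
    derivatives and construction of sampler drift fields from arbitrary target
    densities; Euler-Maruyama integration of fractional Hamiltonian samplers; a
    two-dimensional conductance-based spiking network of excitatory and
    inhibitory neurons whose localized activity pattern performs the sampling;
    trajectory and spike-train diagnostics (center-of-mass tracking, mean
    squared displacement, tail-index estimation, Fano factors, spectra, exit
    times, Burr and gamma dominance-duration fits); and closed-form neural
    field results linking feedforward input and synaptic perturbations to the
    sampler drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
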