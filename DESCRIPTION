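Package: excidisp
Title: Dispersion Energies in Exciton-Localized Excited-State Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the second-order intermolecular dispersion energy for van der
    Waals complexes in which one or both monomers carry a localized electronic
    excitation. Provides a direct sum-over-states engine with a four-way partition of
    the dispersion energy by transition sign, an extended Casimir-Polder engine that
    evaluates the positive-transition block by imaginary-frequency quadrature and the
    de-excitation (non-Casimir-Polder) blocks in closed form, an adiabatic-connection
    route that integrates the coupling-constant-dependent dispersion energy of
    explicit model Hamiltonians, a dispersion-trained reparameterization of the VV10
    nonlocal correlation functional evaluated on molecular quadrature grids with
    counterpoise-corrected interaction energies, assembly and error-metric tools for
    symmetry-adapted perturbation theory (SAPT) component tables, and a small
    s-orbital Gaussian-basis full-configuration-interaction engine that supplies
    exact monomer spectra, transition densities, and density grids for testing every
    formula on real (hydrogenic) molecules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
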