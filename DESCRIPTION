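Package: phosbind
Title: Metal-Nucleotide Binding Analysis from 31P NMR and MD Observables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying magnesium binding to adenosine
    diphosphate (ADP) from 31P NMR observables and molecular-dynamics
    trajectories. Implements fast-exchange two-state and sequential
    three-state population models for chemical-shift titrations,
    exponential fitting of inversion-recovery and echo decays, a
    CSA-dominated spin-lattice relaxation model with inversion for the
    rank-2 rotational correlation time, Stejskal-Tanner diffusion
    fitting, translational (Stokes-Einstein) and rotational
    (Stokes-Einstein-Debye) hydrodynamic radii, distance-trace and
    radial-distribution-function analysis of ion coordination, and
    seeded synthetic-data generators emulating every input so the whole
    pipeline is testable without spectrometer or MD output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
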