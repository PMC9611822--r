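Package: nanolem
Title: Monte Carlo Local Effect Modelling of Gold-Nanoparticle Radiosensitization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for quantifying gold-nanoparticle (AuNP) radiosensitization
    under megavoltage photon beams. Builds radial dose-enhancement-ratio (DER)
    kernels from paired nanoparticle/water-nanoparticle radial dose tables with
    phase-space normalization bookkeeping, places nanoparticles in a 2-D
    cell/nucleus/extracellular-matrix model under homogeneous or cytoplasm-only
    biodistributions, superposes DER dose point kernels on a uniform base dose,
    and evaluates the local effect model (threshold linear-quadratic response)
    by Monte Carlo integration over the nucleus to predict clonogenic survival.
    Includes clonogenic-assay statistics (plating efficiency, survival
    fractions, constrained linear-quadratic fitting with confidence intervals,
    mean inactivation dose, sensitization enhancement ratio) and synthetic-data
    generators with known ground truth for every pipeline input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    MASS
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
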