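Package: mbptip
Title: Many-Body Perturbation Theory for Molecular Ionization Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Diagrammatic many-body perturbation theory (MBPT) for the
    ionization potentials of closed-shell molecular systems described by
    second-quantized Hamiltonians.  Implements the second-order (PT2) and
    GW correlation self-energies, the second-order screened exchange
    (SOSEX) correction, and the linearized GW one-particle density-matrix
    correction, all built on a screened Coulomb interaction obtained from
    a Casida-type linear-response eigenproblem with RPA, TDHF, or
    exchange-scaled hybrid kernels.  Quasiparticle energies are obtained
    by the graphical solution of the quasiparticle equation with spectral
    weights.  Ships a restricted Hartree-Fock solver, FCIDUMP input and
    output, full configuration interaction references for small systems,
    and benchmark-set statistics (mean absolute errors, box and
    whisker summaries with outlier detection).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
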