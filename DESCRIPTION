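Package: coilr
Title: Parametric Modeling, Analysis and Optimization of Coiled Coils and
    Collagen Triple Helices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds all-atom models of alpha-helical coiled coils and
    collagen triple helices from Crick-style structural parameters (radius,
    pitch, interface angle, super-helical rotation, z-shift), analyzes them
    (super-helical parameter fitting from coordinates, SOCKET-style
    knobs-into-holes packing detection and register assignment, soft-core
    inter-chain interaction energies), and optimizes parameters against the
    interaction energy with a Metropolis Monte Carlo sampler, including
    oligomer-state scanning for a sequence. Models are tibbles of atom
    records; results carry tidy() and glance() methods and ggplot2
    autoplot() diagnostics. Includes a PDB reader/writer and a command-line
    interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    pracma,
    withr
Config/testthat/edition: 3
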