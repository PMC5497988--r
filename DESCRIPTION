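Package: cmldyn
Title: Clonal Competition Dynamics of Drug-Resistant CML Under Second-Line TKI Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Deterministic models of the competition between imatinib-resistant
    BCR-ABL1 clones during second-line tyrosine kinase inhibitor therapy.
    Three coupled ODE systems describe cycling stem cells, differentiated
    cells and (optionally) a quiescent clone-1 stem cell pool, with
    exponential negative-feedback growth functions and clone-specific niche
    competition weights. The package integrates the systems with adaptive
    Runge-Kutta methods, locates threshold crossings and extrema of the
    solutions, performs the analytic rescaling, equilibrium classification
    and bifurcation-point computation of the reduced two-clone stem system,
    fits model parameterizations to sparse per-clone BCR-ABL1/GUS time
    series by bounded multi-start nonlinear least squares, and generates
    synthetic patient profiles with clinical-style sparse grids, detection
    limits and multiplicative noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
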