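Package: steadygrad
Title: Adjoint Sensitivities for ODE Models with Steady-State Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gradient engine for maximum-likelihood parameter estimation in
    ODE models of biochemical reaction networks whose experiments involve
    pre- or post-equilibration (steady-state constraints). Implements
    steady-state adjoint sensitivity analysis (ssASA), in which backward
    numerical integration over equilibration intervals is replaced by linear
    solves in the transposed steady-state Jacobian, alongside reference
    gradient methods (standard adjoint, forward sensitivities, finite
    differences), exact conserved-moiety detection and model reduction,
    steady-state equilibration with a weighted-residual convergence test,
    a PEtab-subset problem interface, and multi-start bounded local
    optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
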