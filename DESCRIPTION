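Package: hetnetdyn
Title: Dynamics and Order-Chaos Transitions of Heterogeneous Random Rate Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and mean-field theory for random recurrent rate
    networks of two-variable neurons whose intrinsic parameters (decay rate
    of a slow auxiliary variable and its feedback strength) vary across the
    population, spanning normal, graded-persistent-activity and adaptation
    phenotypes. Provides the analytic prediction of the critical coupling
    strength at which the quiescent state gives way to chaotic activity,
    obtained by averaging the per-neuron transfer gain over the parameter
    distribution in frequency space, together with the numerical
    diagnostics used to locate the transition: the maximum of the
    population-mean power spectral density, the Jacobian eigenspectrum at
    the trivial fixed point, the Benettin maximum Lyapunov exponent, and
    reservoir-computing memory capacity under white-noise drive.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
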