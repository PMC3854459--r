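Package: poolsim
Title: Sequential and Parallel Vesicle Pool Models of Calcium-Dependent Exocytosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and kinetic analysis of calcium-dependent
    neurosecretion in adrenal chromaffin cells. Implements the Sequential
    Pool Model (SPM), in which a calcium-dependent priming catalyst
    accelerates both the forward and reverse NRP-to-RRP priming reactions
    without shifting their equilibrium, alongside the classical Parallel
    Pool Model (PPM) and its catalyst-extended hybrid (PPM+cat). Provides
    adaptive fifth-order Cash-Karp Runge-Kutta integration of either model
    driven by piecewise calcium protocols, analytic resting steady states,
    double-exponential-plus-line decomposition of cumulative capacitance
    traces into fast burst, slow burst and sustained components, a
    closed-form two-pool burst model for SNARE-mutation analysis, and
    scripted in-silico experiments (uncaging flashes, pre- and post-flash
    calcium scans, pool-recovery protocols, synaptotagmin-1-null variants).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
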