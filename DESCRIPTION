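Package: cerenet
Title: Stochastic Simulation of the Cerebellar Network Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Seeded stochastic simulator of a linear model of the cerebellar
    locomotor network: a chain of anatomically constrained random-sampling
    stages that converts frequency distributions of mossy-fibre firing rates
    into synchronized deep-cerebellar-nucleus (DCN) motor output. Implements
    the Golgi-cell ensemble conversion and glomerular spillover inhibition,
    granule-cell activation and self-regulation of the active fraction, the
    parallel-fibre population code, stellate and Purkinje-cell sampling with
    the excitation/inhibition linear inversion, spike-level Purkinje-to-DCN
    convergence with rolling-window readout, the short-term-plasticity phase
    compensation model, and an end-to-end anguilliform-swimming input/output
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
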