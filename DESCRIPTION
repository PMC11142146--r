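Package: trtsim
Title: Mechanistic Simulation and Dose Optimization for Targeted
    Radionuclide Therapy of Disseminated Blood Cancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates targeted radionuclide therapy of disseminated
    blood cancer with a mechanistic ordinary-differential-equation model
    of radiolabeled-antibody pharmacokinetics, irreversible
    antibody-receptor binding, continuous radiation damage of cancer
    cells, and cumulative blood-decay toxicity. Provides closed-form
    surviving-fraction and safe-dose estimates, minimal-curative-dose
    search under toxicity constraints, pharmacokinetic estimation of
    cancer binding capacity, virtual-mouse population generation with
    in-silico trials, maximum-tolerated-dose search, and single- and
    multi-dose treatment schedule optimization. The stiff model dynamics
    are integrated with compiled code through 'deSolve'.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
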