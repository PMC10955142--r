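Package: remfear
Title: Bayesian Simulation of Recent and Remote Context Fear Memory
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates context fear conditioning and its systems
    consolidation from recent (hippocampal) to remote (cortical) memory.
    An agent samples attributes of synthetic contexts, scores candidate
    context representations by a Bayesian weight of evidence built on
    hypergeometric sampling models, creates sparse dentate-gyrus/CA3
    representations by top-K competition, conditions fear at an amygdala
    unit, and transfers memory and fear to localist cortical
    representations through a staged consolidation process. Scripted
    experiments reproduce the immediate shock deficit, pre-exposure
    effect, hyper-generalization of remote fear, its absence for familiar
    or well-known contexts, cross-category hypo-generalization, and the
    reminder effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
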