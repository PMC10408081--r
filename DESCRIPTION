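Package: cetuxcea
Title: Cost-Utility and Budget-Impact Modelling of First-Line Cetuximab for
    Metastatic Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Markov cohort model for first-line cetuximab added to FOLFOX or
    FOLFIRI chemotherapy in KRAS wild-type metastatic colorectal cancer,
    evaluated in the Indonesian setting. Implements a three-state
    (progression-free, progressive, dead) state-transition model with
    time-banded transition probabilities, half-cycle correction and
    discounting; cost-utility analysis with incremental cost-effectiveness
    ratios against a reference chemotherapy strategy; deterministic (tornado)
    and probabilistic sensitivity analysis with cost-effectiveness
    acceptability curves; a five-year payer-perspective budget-impact
    projection with Markov-linked mortality dropout; fixed-effect network
    meta-analysis machinery for relative risks on a star network; and
    seed-deterministic synthetic generators for interview cost records,
    EQ-5D-5L utility records, two-arm trial tables and budget-impact
    epidemiology, so the full pipeline runs end-to-end without access to the
    original patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    ggplot2,
    withr
Config/testthat/edition: 3
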