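Package: netlmm
Title: Edge-Level Mixed-Effects Regression for Weighted Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying small-world reorganization of brain
    subnetworks, in particular the default mode network (DMN), from
    resting-state functional connectivity. Builds weighted connectomes from
    region time series (Pearson correlation, negative weights zeroed,
    short-distance edges excluded), computes Onnela weighted clustering and
    nodal global efficiency, assembles long-format edge designs with
    group x metric x DMN interaction terms, fits subject-random-intercept
    linear mixed models by profiled REML, evaluates group contrast
    statements with Wald inference and two-stage adaptive FDR, and derives
    slope lines, cognition-moderated slope surfaces, and representative
    networks from the fitted models. A synthetic-cohort generator with
    known generative coefficients makes every stage testable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
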