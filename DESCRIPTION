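Package: prevsae
Title: Small-Area Estimation of Survey Prevalence via Multilevel Logistic Models
Version: 0.1.0
Authors@R:
    person("prevsae", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Model-based small-area estimation for binary survey indicators
    collected under a multistage design (individuals nested in clusters,
    districts or constituencies, and states). Fits a four-level
    random-intercept logistic model by first-order marginal quasi-likelihood
    (MQL1) for starting values followed by Metropolis-within-Gibbs MCMC with
    parameter expansion for the cluster variance, turns posterior draws into
    precision-weighted (shrinkage) cluster predicted probabilities, aggregates
    them to area prevalence with 95 percent credible intervals, and derives
    headcounts, direction-adjusted ranks and deciles, and between-round change
    categories. Includes a synthetic multistage survey generator, planar
    geometry fixtures with point-in-polygon cluster reassignment bookkeeping,
    a five-sheet results workbook exporter, and a pipeline command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
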