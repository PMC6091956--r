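Package: pppRank
Title: Cost-Efficiency Prioritization of Threatened-Species Management Projects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Project Prioritization Protocol (PPP) for
    portfolios of threatened-species management projects: benefit as the
    marginal gain in 100-year population viability, likelihood of success as
    the product of per-action implementation and outcome probabilities, cost
    as the 50-year net present value of all scheduled actions with
    apportionment of costs shared between co-located projects, and the
    cost-efficiency priority score benefit x likelihood / cost. Provides
    budget-constrained iterative portfolio selection with dynamic dissolution
    of cost-sharing, Monte Carlo propagation of expert-elicitation uncertainty
    through triangular distributions into 95% rank likelihood intervals and
    five priority bands, per-parameter sensitivity analysis, and a synthetic
    portfolio generator emulating the statistical structure of a state-wide
    threatened-species program.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'accessors.R'
    'io.R'
    'scoring.R'
    'costSharing.R'
    'portfolio.R'
    'uncertainty.R'
    'synthetic.R'
    'pipeline.R'
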