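Package: lagnma
Title: Bayesian Fixed-Effects Network Meta-Analysis of Long-Acting Growth
    Hormones in Pediatric Growth Hormone Deficiency
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for aggregate-data Bayesian network meta-analysis of
    long-acting growth hormone (LAGH) therapies versus daily somatropin in
    treatment-naive pediatric growth hormone deficiency. Implements the NICE
    Decision Support Unit generalized linear modelling framework with fixed
    treatment effects: an arm-based normal likelihood for continuous outcomes
    (mean differences) and a binomial-logit likelihood for binary outcomes
    (odds ratios), sampled by Markov chain Monte Carlo with convergence
    diagnostics. Includes preprocessing of arm-level trial summaries
    (standard-error reconstruction from credible intervals,
    change-from-baseline SD imputation via a pooled baseline/follow-up
    correlation), evidence-network construction with feasibility rules,
    SUCRA treatment rankings, league tables, a synthetic-trial generator
    with known ground truth, and a reproducible reporting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    rjags,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
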