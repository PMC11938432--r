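# lagnma

Bayesian fixed-effects network meta-analysis (NMA) of long-acting growth
hormones (LAGHs) versus daily somatropin in treatment-naive pediatric growth
hormone deficiency (pGHD).

Once-weekly LAGHs — lonapegsomatropin, somapacitan, somatrogon, LB03002 —
have never been compared head-to-head: each phase-3 trial compares one LAGH
against daily somatropin at 52 weeks. Because every trial shares the daily
somatropin comparator, the trials form a star-shaped evidence network, and
relative effects *between* LAGHs can be estimated indirectly. `lagnma` is
aimed at evidence-synthesis statisticians who want that analysis to be
reproducible end to end from arm-level aggregate summaries: annualized
height velocity (cm/year), change from baseline in height SDS, in weekly
average IGF-1 SDS, and in bone age-to-chronological age ratio, plus serious
adverse events.

## Model

The engine implements the arm-based generalized linear modelling framework
of the NICE Decision Support Unit with fixed treatment effects. For trial
*i*, arm *k* with treatment *t(i,k)*:

- continuous outcomes (identity link, known arm SE):
  `y_ik ~ Normal(mu_i + d_t(i,k) - d_t(i,1), se_ik^2)`
- binary outcomes (logit link, exact binomial likelihood, no continuity
  correction): `r_ik ~ Binomial(n_ik, p_ik)`,
  `logit(p_ik) = mu_i + d_t(i,k) - d_t(i,1)`

`mu_i` are trial-baseline nuisance parameters and `d_k` the basic parameters
(relative effect of treatment *k* vs daily somatropin, the network
reference, fixed at 0). Under consistency every pairwise contrast is
`d_A - d_B`. Priors are vague normals, `N(0, 100^2)` on the model scale.
Posteriors are sampled by MCMC (exact joint Gaussian draws for the conjugate
continuous model; adaptive random-walk Metropolis-within-Gibbs for the
binomial model) with split-chain potential-scale-reduction and
effective-sample-size gates. Results are posterior medians of mean
differences (MD) or odds ratios (OR) with 95% credible intervals, SUCRA
scores, and probability-best rankings.

Supporting machinery covers the unglamorous parts: standard errors
reconstructed from printed 95% interval spans (`se = width / (2 * 1.959964)`),
change-from-baseline SDs imputed through a pooled baseline/follow-up
correlation `sd_c = sqrt(sd_b^2 + sd_f^2 - 2 r sd_b sd_f)`, evidence-network
feasibility rules (at least 2 studies per outcome and scenario, 52-week data
only, connected network), and an inverse-variance frequentist oracle used to
validate the sampler.

## Worked example

The bundled fixtures reconstruct the base-case network (three trials:
lonapegsomatropin, somatrogon, somapacitan, each vs daily somatropin; see
`inst/extdata/README.md` for provenance):

```r
library(lagnma)

trials <- read_trials(lagnma_extdata("base_case.csv"))
r <- estimate_correlation(complete_sd_triples(trials))
net <- build_network(trials, "igf1_sds", scenario("base"))
fit <- fit_continuous(net, nma_model_spec("continuous", seed = 1),
                      correlation = r)
est <- summarize_effects(fit)
subset(cbind(est, significant = flag_significance(est)),
       treatment_b == "daily_somatropin")
rank_treatments(fit)
```

```
         treatment_a      treatment_b scale point cri_lower cri_upper significant
4  lonapegsomatropin daily_somatropin    md 0.859     0.609      1.11        TRUE
7        somapacitan daily_somatropin    md 0.031    -0.310      0.37       FALSE
10        somatrogon daily_somatropin    md 1.569     1.277      1.86        TRUE

<ranking_result> outcome 'igf1_sds' (higher is better)
  somatrogon         SUCRA 100%  P(best) 1.00  E[rank] 1.00
  lonapegsomatropin  SUCRA  67%  P(best) 0.00  E[rank] 2.00
  somapacitan        SUCRA  19%  P(best) 0.00  E[rank] 3.43
  daily_somatropin   SUCRA  14%  P(best) 0.00  E[rank] 3.57
```

Reading: somatrogon raises weekly average IGF-1 SDS over 52 weeks by a
posterior median of 1.57 SDS units more than daily somatropin (95% CrI
1.28–1.86, credibly non-zero), and is essentially certain to rank first on
this pharmacodynamic outcome (SUCRA 100%); the somapacitan contrast is
compatible with no difference. `run_pipeline()` executes the same analysis
for every outcome and scenario and writes network exports, estimate tables,
league tables, ranking tables, and a run manifest.

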