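---
title: "Methods: fixed-effects network meta-analysis of long-acting growth hormones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fixed-effects network meta-analysis of long-acting growth hormones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagnma)
```

## The estimation problem

Pediatric growth hormone deficiency is treated with daily somatropin or one
of several once-weekly long-acting growth hormones (LAGHs). The LAGHs are
molecularly distinct — albumin-binding (somapacitan), fusion-protein
(somatrogon), prodrug (lonapegsomatropin), depot (LB03002) — and have never
been compared directly. Every usable phase-3 trial is a two-arm, open-label
comparison of one LAGH against daily somatropin at approved doses with
52-week outcomes. Joint analysis of these trials yields a star-shaped
evidence network with daily somatropin at the hub, and relative effects
between LAGHs are estimable only indirectly, through the consistency
relation `MD(A, B) = MD(A, ref) - MD(B, ref)`.

`lagnma` implements that analysis as a pipeline: arm-level aggregate
summaries in, posterior contrasts, credible intervals and SUCRA rankings
out, with the preprocessing, feasibility and diagnostic rules stated
explicitly and tested.

## Data model and feasibility rules

Inputs are one row per trial × arm × outcome (`read_trials()`), with missing
cells encoded as empty strings — `0` is always a value, never a missing
marker. Five outcomes are modelled: annualized height velocity (`ahv`,
cm/year), change from baseline in height SDS (`height_sds`), in weekly
average IGF-1 SDS (`igf1_sds`), in bone age-to-chronological age ratio
(`ba_ca_ratio`), and serious adverse events (`sae`, binary). `ahv` is
analyzed as the 52-week *value*, the other continuous outcomes as change
from baseline; the per-arm analysis measure is selected accordingly.

Three analytic scenarios are predefined: the base case (the three
design-comparable trials), sensitivity analysis 1 (base + the LB03002
trial), and sensitivity analysis 2 (base + the second, Japanese somatrogon
trial with its lower daily somatropin dose). `build_network()` enforces the
feasibility rules as hard gates rather than conventions:

- only 52-week data enter an analysis;
- an outcome is analyzable in a scenario only if at least 2 included studies
  report it (classed `lagnma_feasibility_error` otherwise);
- fitting refuses disconnected networks.

The approved-dose eligibility criterion is carried as data (trials included
in the shipped scenarios used approved doses); it is not re-derived from
regulatory sources, which are not computable.

## Preprocessing

Aggregate reporting is incomplete in this literature, so two reconstruction
devices are first-class, flagged operations rather than silent defaults:

- **SEs from printed intervals.** A normal approximation recovers
  `se = (upper - lower) / (2 z)`, `z = 1.959964` (kept at full precision
  rather than 1.96 so reconstructions are reproducible to more digits than
  the printed intervals). `se_from_interval()` is location-invariant and
  linear in interval width, and both properties are tested.
- **Change-SD imputation.** Where a change-from-baseline SD is unreported
  but baseline and follow-up SDs exist,
  `sd_c = sqrt(sd_b^2 + sd_f^2 - 2 r sd_b sd_f)`. The correlation `r` is
  pooled across all complete (baseline, follow-up, change) SD triples in the
  data set as the *unweighted mean* of the per-triple implied correlations,
  clamped to [-1, 1]. The pooling rule is a package choice — the source
  analyses state only that `r` was estimated from complete pairs across
  outcomes, not how they were combined — and the unweighted mean is the
  simplest defensible reading. A reported change SD always wins over an
  imputable one; imputation is a fallback, and `preprocessing_ledger()`
  records reported/imputed/unavailable status per arm × outcome so the
  compounding of uncertainty stays visible.

The two operations are exact mutual inverses, verified to 1e-12 in the test
suite.

## The model

Arm-based generalized linear models in the NICE DSU style with fixed
treatment effects. Trial baselines `mu_i` are nuisance parameters; basic
parameters `d_k` are relative effects versus daily somatropin (reference
fixed at 0); the linear predictor of arm (i, k) is
`mu_i + d_t(i,k) - d_t(i,1)`.

- **Continuous outcomes:** identity link, `y_ik ~ N(theta_ik, se_ik^2)` with
  `se_ik = sd_ik / sqrt(n_ik)` treated as known.
- **Binary outcomes:** logit link with the exact binomial likelihood. No
  continuity correction is applied: SAE counts are small, a normal
  approximation would be poor, and zero-event arms are handled by the
  likelihood itself, which remains proper under the priors.

Only fixed effects are offered. With at most one or two studies per
contrast, a between-study heterogeneity variance is not identifiable, and
node-splitting consistency checks are impossible in a pure star; both are
deliberate non-goals rather than omissions.

The arm-based parameterization (trial baselines as nuisance) and the
contrast-based alternative give identical fixed-effects estimates for
two-arm trials; arm-based was chosen because it generalizes to multi-arm
trials, which the data model accepts and the engine edge-expands per arm
pair (tested on synthetic three-arm trials).

### Priors

`N(0, 100^2)` on the model scale (outcome units or log-odds) for both `d_k`
and `mu_i`, configurable via `nma_model_spec()`. The source analyses name
the modelling framework but not their priors; the vague-normal default is
the standard convention for that framework. At the SEs occurring here
(0.06–0.4), the prior contributes precision of order 1e-4 against likelihood
precision of order 10–100, so prior shrinkage is far below the Monte Carlo
resolution of the reported summaries.

### Sampling and diagnostics

Defaults: 4 chains × 20 000 iterations, 5 000 burn-in, no thinning (60 000
retained draws), explicit integer seed; identical spec + seed gives
bit-identical draws.

- The **continuous** model is fully conjugate: the joint posterior of
  `(d, mu)` is multivariate Gaussian in closed form, so the sampler draws
  the entire parameter block jointly per iteration via a Cholesky factor of
  the posterior precision — exact, independent draws (a one-block Gibbs
  sampler). This was a deliberate design choice over parameter-at-a-time
  updating, whose mixing degrades when trials connect two non-reference
  treatments and the basic parameters become correlated a posteriori; joint
  draws make mixing pathologies structurally impossible while keeping the
  same posterior contract.
- The **binary** model has no conjugate structure and uses single-site
  random-walk Metropolis-within-Gibbs, with per-parameter step sizes adapted
  toward a 0.44 acceptance rate during burn-in only (so the retained chain
  is a fixed-kernel Markov chain).

Every fit computes split-chain potential scale reduction and effective
sample sizes (via `coda`). Runs fail loudly — classed
`lagnma_convergence_error` — if any basic parameter has split-Rhat > 1.05 or
ESS < 400. The sources report no convergence criteria; a gate was required
for reproducibility and these are conventional thresholds.

Posterior point estimates are **medians** (matching the reported summaries),
with central 95% credible intervals from the 2.5th/97.5th percentiles;
odds-ratio summaries exponentiate the per-draw log-odds contrasts, so
antisymmetry (`MD(A,B) = -MD(B,A)`, `OR(A,B) = 1/OR(B,A)`) holds draw by
draw, exactly.

### The frequentist oracle

`frequentist_oracle()` computes the inverse-variance weighted-least-squares
network estimator from trial-level direct estimates. For the normal
likelihood with vague priors the Bayesian posterior coincides with it, which
gives an independent validation route: the test suite checks agreement of
posterior medians and intervals on 50 random connected networks (K ≤ 5,
≤ 8 trials) to ±0.02. The oracle is never the implementation, only the
check; the binary model is additionally cross-checked against an
independent MCMC engine (JAGS) on a single-trial example.

## Rankings

Within each retained draw, treatments are ranked on `d` — descending for
benefit outcomes (`ahv`, `height_sds`, `igf1_sds`), ascending for harms
(`sae`). Bone-age advancement is configurable with a lower-is-better
default: untoward bone-age progression risks premature growth-plate
closure, but the benefit/harm reading of this outcome is genuinely
arguable, so the direction is a parameter rather than a constant. Exact
ties are measure-zero under the continuous posterior and are broken
deterministically by treatment id order.

SUCRA is computed from the rank-probability matrix as the normalized area
under the cumulative ranking curve,
`sucra_k = (1/(K-1)) * sum_{j<K} P(rank_k <= j)`; probability-best is the
first column of that matrix. Algebraic identities — mean SUCRA exactly 0.5,
SUCRA = probability-best at K = 2, invariance to per-draw common shifts —
are tested. SUCRA is displayed as a whole percent in report tables and kept
at full precision in objects.

## Synthetic data

The generator simulates *individual patients* and then aggregates, so the
summary-level structure the analysis assumes is emergent, not asserted:
correlated bivariate-normal (baseline, follow-up) pairs with correlation
`r_true` per arm for continuous outcomes, binomial event counts on the
logit scale for binary ones. This makes the change-SD imputation honestly
testable — aggregated SDs reproduce
`sd_c^2 = sd_b^2 + sd_f^2 - 2 r sd_b sd_f` only up to sampling error, which
is what real aggregate data would do.

`make_paper_like_network()` reproduces the study conditions: three (or, with
a sensitivity flag, four) two-arm trials, one LAGH each versus daily
somatropin, with the published analyzed arm sizes (56–132 per arm; 22 in the
small Japanese trial) and default true effects equal to the published direct
IGF-1 SDS contrasts (0.86, 1.57, and 0.03 by consistency). Where no
published value exists (the LB03002 effect, baseline levels, `r_true = 0.6`)
a single realistic value was fixed once and documented here. The generator
does **not** emulate dropout, dose titration, visit-window jitter, outcome
digitization error, or between-study heterogeneity — so passing recovery
tests demonstrate correctness of the estimator under its own assumptions,
not robustness to the ways real aggregate data violate them.

`trial_from_direct()` is the deterministic bridge used in worked examples:
it builds a two-arm trial whose arm summaries reproduce a target MD and SE
exactly (`sd = se * sqrt(n/2)` per arm), which is how published
contrast-level results are turned back into analyzable arm-level inputs.

## Fixtures and reproduction of published results

The arm-level 52-week data behind the published analysis are not publicly
deposited, so the bundled fixtures are labelled reconstructions (see
`inst/extdata/README.md`): printed contrast-level estimates in
`direct_estimates.csv`; arm-level cells either derived (chosen so
trial-level direct estimates reproduce printed contrasts and interval
widths), or synthetic (plausible values completing the data model, with
published trial sizes and baseline summaries where printed). Consequently
the base-case IGF-1 SDS network built from fixtures reproduces all five
published contrasts, and the single-trial growth-outcome examples reproduce
theirs, while outcomes without printed direct estimates are exercised
structurally, not numerically. The pooled correlation from the fixture
triples is likewise a property of the reconstruction: the published value
of `r` was never reported, so only the estimator's algebra is verifiable.

## Numerical choices and problem sizes

- Normal quantile for 95% intervals fixed at `qnorm(0.975)` = 1.959964.
- Correlation estimates clamped to [-1, 1]; imputed variances floored at 0.
- CSV round-trips preserve doubles bit-identically (17-significant-digit
  fallback formatting).
- Worked-example fits use 60 000 retained draws (Monte Carlo error of a
  posterior median ≈ 0.001 at the posterior SDs involved, against reporting
  tolerances of ±0.02–0.03). The oracle-equivalence suite uses 16 000
  retained draws per network and the coverage study 8 000 per replicate
  across 200 replicates of the base-case-shaped network — sizes chosen so
  each suite's Monte Carlo error stays an order of magnitude below the
  property's tolerance.

## Known limitations

- Fixed effects only; heterogeneity and inconsistency are not estimable in
  networks this sparse, and the package does not pretend otherwise.
- The normal-likelihood treatment of arm summaries assumes large-enough arm
  sizes for the CLT at the summary level; no small-sample t adjustments or
  bias corrections are offered.
- Interval-based SE reconstruction assumes symmetric normal intervals; a
  markedly asymmetric printed interval would signal a scale mismatch the
  package does not attempt to repair.
- The SAE model treats "any event by 52 weeks" as exchangeable across
  trials; differing SAE definitions are a data-quality issue upstream of
  the model.
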