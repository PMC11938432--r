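# Shared test helpers: hand-built posterior objects and small networks.

# minimal nma_draws object with prescribed basic-parameter draws
fake_draws <- function(d, reference = colnames(d)[1], scale = "md",
                       outcome = NULL) {
  structure(list(d = d, mu = NULL, sims = NULL,
                 treatments = colnames(d), reference = reference,
                 outcome = outcome, scale = scale, spec = NULL,
                 diagnostics = NULL),
            class = "nma_draws")
}

# two-arm binary trial record
binary_trial <- function(trial_id, treatment, n1, r1, n0, r0,
                         reference = "daily_somatropin") {
  trial_record(trial_id, 52, list(
    list(treatment = treatment, outcomes = list(sae = binary_arm(n1, r1))),
    list(treatment = reference, outcomes = list(sae = binary_arm(n0, r0)))))
}

# star network of deterministic continuous trials, one LAGH each vs reference
star_trials <- function(effects, ses, outcome = "igf1_sds", n = 100) {
  trts <- names(effects)
  lapply(seq_along(effects), function(i) {
    trial_from_direct(paste0("trial", i), trts[i], effects[i], ses[i],
                      outcome = outcome, n = n)
  })
}

custom_net <- function(trials, outcome = "igf1_sds",
                       reference = "daily_somatropin", min_studies = 1L) {
  ids <- vapply(trials, function(t) t$trial_id, character(1))
  build_network(trials, outcome, scenario("custom", ids),
                reference = reference, min_studies = min_studies)
}

quick_spec <- function(kind = "continuous", seed = 1, iterations = 4000,
                       burn_in = 1000, ...) {
  nma_model_spec(kind, seed = seed, iterations = iterations,
                 burn_in = burn_in, ...)
}
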