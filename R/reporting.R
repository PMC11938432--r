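# League tables, significance flags and the end-to-end reporting pipeline.

#' Flag statistical significance of effect estimates
#'
#' An estimate is flagged significant when its 95\% credible interval excludes
#' the null value: 0 for mean differences, 1 for odds ratios.
#'
#' @param est An `effect_estimates` data.frame from [summarize_effects()]
#'   (or any data.frame with `scale`, `cri_lower`, `cri_upper`).
#' @return Logical vector, one flag per row.
#' @export
flag_significance <- function(est) {
  null_value <- ifelse(est$scale == "or", 1, 0)
  null_value < est$cri_lower | null_value > est$cri_upper
}

#' League table of all pairwise contrasts
#'
#' Square table over the network treatments: the (row, column) cell holds the
#' posterior median effect of row vs column with its 95\% credible interval
#' and significance flag. The table is antisymmetric under transposition
#' (points negate on the mean-difference scale, invert on the odds-ratio
#' scale).
#'
#' @param draws An `nma_draws` object.
#' @param scale `"md"` or `"or"` (default: the model's natural scale).
#' @param order Treatment ordering for rows/columns; defaults to the
#'   network order (reference first).
#' @return An object of class `league_table` with matrices `point`, `lower`,
#'   `upper`, `significant`.
#' @export
league_table <- function(draws, scale = NULL, order = NULL) {
  est <- summarize_effects(draws, scale)
  trts <- order %||% draws$treatments
  stopifnot(setequal(trts, draws$treatments))
  K <- length(trts)
  point <- lower <- upper <- matrix(
    if (est$scale[1] == "or") 1 else 0, K, K, dimnames = list(trts, trts))
  sig <- matrix(FALSE, K, K, dimnames = list(trts, trts))
  est$sig <- flag_significance(est)
  for (i in seq_len(nrow(est))) {
    a <- est$treatment_a[i]; b <- est$treatment_b[i]
    point[a, b] <- est$point[i]
    lower[a, b] <- est$cri_lower[i]
    upper[a, b] <- est$cri_upper[i]
    sig[a, b] <- est$sig[i]
  }
  structure(list(treatments = trts, scale = est$scale[1], point = point,
                 lower = lower, upper = upper, significant = sig),
            class = "league_table")
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  cat(sprintf("<league_table> %s scale (row vs column); * = 95%% CrI excludes %s\n",
              toupper(x$scale), if (x$scale == "or") "1" else "0"))
  K <- length(x$treatments)
  cells <- matrix("", K, K, dimnames = dimnames(x$point))
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) { cells[i, j] <- x$treatments[i]; next }
    cells[i, j] <- sprintf("%s%.*f (%.*f, %.*f)",
                           if (x$significant[i, j]) "*" else "",
                           digits, x$point[i, j], digits, x$lower[i, j],
                           digits, x$upper[i, j])
  }
  print(cells, quote = FALSE)
  invisible(x)
}

#' Export a league table as CSV
#'
#' Long format: one row per ordered contrast with point, CrI and significance.
#'
#' @param lt A [league_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_league_csv <- function(lt, path) {
  rows <- list()
  for (a in lt$treatments) for (b in lt$treatments) {
    if (a == b) next
    rows[[length(rows) + 1L]] <- data.frame(
      treatment_a = a, treatment_b = b, scale = lt$scale,
      point = lt$point[a, b], cri_lower = lt$lower[a, b],
      cri_upper = lt$upper[a, b], significant = lt$significant[a, b],
      stringsAsFactors = FALSE)
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full NMA reporting pipeline
#'
#' For each requested outcome: build the evidence network for the scenario,
#' fit the fixed-effects model (continuous or binary by outcome kind), and
#' write per-outcome artifacts into `outdir`: network edge list and DOT
#' diagram, effect-estimate table, league table, ranking table, and a run
#' manifest JSON recording the model spec, seed, convergence diagnostics and
#' input-file hash. Failures carry classed conditions
#' (`lagnma_feasibility_error`, `lagnma_convergence_error`,
#' `lagnma_validation_error`).
#'
#' @param config A list (or path to a JSON file) with elements:
#'   `input_csv` (path to the trial-summary CSV), `scenario` (name or
#'   [scenario()] trial ids), `outcomes` (default: all outcomes reported by
#'   at least two trials are attempted), optional `model` overrides
#'   (`prior_sd_d`, `prior_sd_mu`, `chains`, `iterations`, `burn_in`),
#'   optional `ba_ca_ratio_direction`.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed overriding `config$seed` (default 1).
#' @param write_draws If `TRUE`, also export retained draws per outcome.
#' @return Invisibly, a list of per-outcome results (`network`, `draws`,
#'   `estimates`, `ranking`).
#' @export
run_pipeline <- function(config, outdir, seed = NULL, write_draws = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config), !is.null(config$input_csv))
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  trials <- read_trials(config$input_csv)
  violations <- unlist(lapply(trials, validate_record))
  if (length(violations)) {
    stop(validation_error(paste(violations, collapse = "; ")))
  }
  sc <- if (is.null(config$scenario) || is.character(config$scenario) &&
            config$scenario[1] %in% c("base", "sa1", "sa2")) {
    scenario(config$scenario %||% "base")
  } else {
    scenario("custom", trial_ids = config$scenario)
  }
  outcomes <- config$outcomes %||% lagnma_outcomes()
  triples <- complete_sd_triples(trials)
  rcorr <- if (nrow(triples) > 0) estimate_correlation(triples) else NULL
  model_cfg <- config$model %||% list()
  results <- list()
  for (oc in outcomes) {
    net <- build_network(trials, oc, sc)
    kind <- outcome_kind(oc)
    spec <- nma_model_spec(
      kind,
      prior_sd_d = model_cfg$prior_sd_d %||% 100,
      prior_sd_mu = model_cfg$prior_sd_mu %||% 100,
      chains = model_cfg$chains %||% 4L,
      iterations = model_cfg$iterations %||% 20000L,
      burn_in = model_cfg$burn_in %||% 5000L,
      seed = seed + match(oc, lagnma_outcomes()))
    draws <- if (kind == "binary") {
      fit_binary(net, spec)
    } else {
      fit_continuous(net, spec, correlation = rcorr)
    }
    est <- summarize_effects(draws)
    ranking <- rank_treatments(
      draws, outcome_direction(oc, config$ba_ca_ratio_direction %||% "lower"))
    stem <- file.path(outdir, paste0(oc, "_", sc$name))
    write_network_csv(net, paste0(stem, "_network.csv"))
    writeLines(network_dot(net), paste0(stem, "_network.dot"))
    est_out <- est
    est_out$significant <- flag_significance(est_out)
    write.csv(est_out, paste0(stem, "_estimates.csv"), row.names = FALSE,
              quote = FALSE)
    write_league_csv(league_table(draws), paste0(stem, "_league.csv"))
    write_ranking_csv(ranking, paste0(stem, "_ranking.csv"))
    if (write_draws) write_draws_csv(draws, paste0(stem, "_draws.csv"))
    manifest <- list(
      outcome = oc, scenario = sc$name, seed = spec$seed,
      model = spec[c("outcome_kind", "effects", "prior_sd_d", "prior_sd_mu",
                     "chains", "iterations", "burn_in")],
      input_csv = basename(config$input_csv),
      input_md5 = unname(tools::md5sum(config$input_csv)),
      correlation = if (is.null(rcorr)) NULL else
        list(r = rcorr$r, n_pairs = rcorr$n_pairs),
      diagnostics = draws$diagnostics)
    jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results[[oc]] <- list(network = net, draws = draws, estimates = est,
                          ranking = ranking)
  }
  invisible(results)
}
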