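# Preprocessing of aggregate summaries: everything between the published
# tables and the quantities the likelihood needs.

#' Standard error from a reported confidence/credible interval
#'
#' Reconstructs the standard error of a normally-distributed estimate from the
#' span of its printed central interval: `se = (upper - lower) / (2 * z)` with
#' `z` the standard-normal quantile at `(1 + level) / 2` (1.959964 for 95%).
#'
#' @param lower,upper Interval bounds, `upper >= lower`.
#' @param level Interval coverage in (0, 1); default 0.95.
#' @return Standard error (vectorized).
#' @export
#' @examples
#' se_from_interval(0.19, 1.61) # 0.36225
se_from_interval <- function(lower, upper, level = 0.95) {
  if (any(level <= 0 | level >= 1)) {
    stop("`level` must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(upper < lower)) {
    stop("interval upper bound below lower bound", call. = FALSE)
  }
  z <- qnorm((1 + level) / 2)
  (upper - lower) / (2 * z)
}

#' Impute a change-from-baseline SD from baseline and follow-up SDs
#'
#' When a trial reports baseline and follow-up SDs but not the SD of the
#' change, the change SD follows from the variance of a difference of
#' correlated quantities:
#' `sd_change = sqrt(sd_baseline^2 + sd_followup^2 - 2 r sd_baseline sd_followup)`,
#' with `r` the baseline/follow-up correlation (pooled across complete
#' observations by [estimate_correlation()]).
#'
#' @param sd_baseline,sd_followup Reported SDs, both > 0.
#' @param r Correlation in `[-1, 1]`.
#' @return Imputed change SD (>= 0, vectorized).
#' @export
impute_change_sd <- function(sd_baseline, sd_followup, r) {
  if (any(abs(r) > 1)) stop("|r| must be <= 1", call. = FALSE)
  if (any(sd_baseline <= 0) || any(sd_followup <= 0)) {
    stop("SDs must be > 0", call. = FALSE)
  }
  sqrt(pmax(0, sd_baseline^2 + sd_followup^2 - 2 * r * sd_baseline * sd_followup))
}

#' Pool the baseline/follow-up correlation from complete triples
#'
#' For every arm x outcome where baseline, follow-up and change SDs are all
#' reported, the implied correlation is
#' `r_i = (sd_b^2 + sd_f^2 - sd_c^2) / (2 sd_b sd_f)`. The pooled estimate is
#' the unweighted mean of the per-triple correlations, clamped to `[-1, 1]`.
#'
#' @param triples A data.frame (or matrix) with columns `sd_baseline`,
#'   `sd_followup`, `sd_change`; one row per complete triple.
#' @return An object of class `correlation_estimate` with fields `r`,
#'   `n_pairs`, and the per-triple correlations `r_i`.
#' @export
estimate_correlation <- function(triples) {
  triples <- as.data.frame(triples)
  if (nrow(triples) == 0L) {
    stop("at least one complete triple is required", call. = FALSE)
  }
  req <- c("sd_baseline", "sd_followup", "sd_change")
  if (!all(req %in% names(triples))) {
    stop("`triples` needs columns sd_baseline, sd_followup, sd_change",
         call. = FALSE)
  }
  b <- triples$sd_baseline; f <- triples$sd_followup; c_ <- triples$sd_change
  if (any(b <= 0) || any(f <= 0) || any(c_ < 0)) {
    stop("SDs must be positive (change SD non-negative)", call. = FALSE)
  }
  ri <- (b^2 + f^2 - c_^2) / (2 * b * f)
  r <- min(1, max(-1, mean(ri)))
  structure(list(r = r, n_pairs = nrow(triples), r_i = ri),
            class = "correlation_estimate")
}

#' @export
print.correlation_estimate <- function(x, ...) {
  cat(sprintf("<correlation_estimate> r = %.4f from %d complete pair(s)\n",
              x$r, x$n_pairs))
  invisible(x)
}

#' Collect complete SD triples from trial records
#'
#' Scans all arms and continuous outcomes for rows reporting baseline,
#' follow-up and change SDs together; these feed [estimate_correlation()].
#'
#' @param records List of [trial_record()] objects.
#' @return A data.frame of complete triples, with `trial_id`, `treatment`,
#'   `outcome` bookkeeping columns.
#' @export
complete_sd_triples <- function(records) {
  rows <- list()
  for (rec in records) {
    for (a in rec$arms) {
      for (oc in names(a$outcomes)) {
        s <- a$outcomes[[oc]]
        if (inherits(s, "continuous_arm") &&
            !is.na(s$baseline_sd) && !is.na(s$followup_sd) &&
            !is.na(s$change_sd)) {
          rows[[length(rows) + 1L]] <- data.frame(
            trial_id = rec$trial_id, treatment = a$treatment, outcome = oc,
            sd_baseline = s$baseline_sd, sd_followup = s$followup_sd,
            sd_change = s$change_sd, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(trial_id = character(0), treatment = character(0),
                      outcome = character(0), sd_baseline = numeric(0),
                      sd_followup = numeric(0), sd_change = numeric(0)))
  }
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Per-arm analysis measure
# ---------------------------------------------------------------------------

# Select the quantity the likelihood models for one arm: the 52-week value
# for ahv ("value at 52 wk"), change from baseline otherwise. Falls back to
# deriving the change mean from baseline/follow-up means and imputing the
# change SD via the correlation when the change pair is not reported.
arm_measure <- function(summary, outcome, r = NULL) {
  stopifnot(inherits(summary, "continuous_arm"))
  s <- summary
  if (identical(outcome, "ahv")) {
    if (!is.na(s$followup_mean) && !is.na(s$followup_sd)) {
      return(list(mean = s$followup_mean, sd = s$followup_sd, n = s$n,
                  imputed = FALSE))
    }
    if (!is.na(s$change_mean) && !is.na(s$change_sd)) {
      return(list(mean = s$change_mean, sd = s$change_sd, n = s$n,
                  imputed = FALSE))
    }
    stop("ahv arm lacks a follow-up (52-week value) pair", call. = FALSE)
  }
  if (!is.na(s$change_mean) && !is.na(s$change_sd)) {
    # reported change pair always wins; imputation is a fallback only
    return(list(mean = s$change_mean, sd = s$change_sd, n = s$n,
                imputed = FALSE))
  }
  cm <- if (!is.na(s$change_mean)) s$change_mean else {
    if (is.na(s$baseline_mean) || is.na(s$followup_mean)) {
      stop("cannot derive change mean: baseline/follow-up means missing",
           call. = FALSE)
    }
    s$followup_mean - s$baseline_mean
  }
  if (is.na(s$baseline_sd) || is.na(s$followup_sd)) {
    stop("cannot impute change SD: baseline/follow-up SDs missing",
         call. = FALSE)
  }
  if (is.null(r)) {
    stop("change SD missing and no correlation estimate supplied",
         call. = FALSE)
  }
  rv <- if (inherits(r, "correlation_estimate")) r$r else as.numeric(r)
  list(mean = cm, sd = impute_change_sd(s$baseline_sd, s$followup_sd, rv),
       n = s$n, imputed = TRUE)
}

# ---------------------------------------------------------------------------
# Trial-level direct estimates
# ---------------------------------------------------------------------------

#' Direct estimate constructor
#'
#' A trial-level contrast `A` minus `B` on the mean-difference (or log-odds)
#' scale with its standard error. "A vs B" means A - B throughout; in the
#' shipped networks A is the LAGH and B daily somatropin.
#'
#' @param trial_id Trial token (or a label for reconstructed estimates).
#' @param treatment_a,treatment_b The contrasted treatments (A minus B).
#' @param md Mean difference (A - B).
#' @param se Standard error, > 0.
#' @param source `"measured"` or `"reconstructed-from-interval"`.
#' @return An object of class `direct_estimate`.
#' @export
direct_estimate <- function(trial_id, treatment_a, treatment_b, md, se,
                            source = c("measured", "reconstructed-from-interval")) {
  source <- match.arg(source)
  if (!is.finite(se) || se <= 0) stop("se must be > 0", call. = FALSE)
  structure(list(trial_id = tolower(trial_id),
                 treatment_a = tolower(treatment_a),
                 treatment_b = tolower(treatment_b),
                 md = as.numeric(md), se = as.numeric(se), source = source),
            class = "direct_estimate")
}

#' @export
print.direct_estimate <- function(x, ...) {
  cat(sprintf("<direct_estimate> %s: %s vs %s, MD %.4f (SE %.5f) [%s]\n",
              x$trial_id, x$treatment_a, x$treatment_b, x$md, x$se, x$source))
  invisible(x)
}

#' Trial-level direct estimate of a continuous outcome contrast
#'
#' For a two-arm trial reporting the outcome in both arms:
#' `md = mean_A - mean_B` and `se = sqrt(sd_A^2/n_A + sd_B^2/n_B)`, where the
#' per-arm mean/SD are the analysis measure for the outcome (52-week value for
#' annualized height velocity, change from baseline otherwise) and change SDs
#' are imputed through `r` only where unreported.
#'
#' @param trial A [trial_record()].
#' @param outcome A continuous outcome id.
#' @param r Correlation used for change-SD imputation
#'   ([estimate_correlation()] result or a plain number); only needed when an
#'   arm lacks a reported change SD.
#' @param reference Treatment id taken as B (the subtrahend) when present in
#'   the trial; defaults to daily somatropin.
#' @return A [direct_estimate()] with an `imputed` attribute flagging arms
#'   whose change SD was imputed.
#' @export
trial_direct_estimate <- function(trial, outcome, r = NULL,
                                  reference = "daily_somatropin") {
  stopifnot(inherits(trial, "trial_record"))
  if (outcome_kind(outcome) != "continuous") {
    stop("trial_direct_estimate handles continuous outcomes", call. = FALSE)
  }
  has <- vapply(trial$arms, function(a) outcome %in% names(a$outcomes),
                logical(1))
  if (sum(has) != 2L) {
    stop(feasibility_error(sprintf(
      "trial '%s' must report outcome '%s' in exactly 2 arms (found %d)",
      trial$trial_id, outcome, sum(has))))
  }
  arms <- trial$arms[has]
  trts <- vapply(arms, function(a) a$treatment, character(1))
  # B is the reference arm when present, otherwise the lexicographically later id
  b_idx <- if (tolower(reference) %in% trts) {
    which(trts == tolower(reference))
  } else {
    which(trts == sort(trts)[2])
  }
  a_idx <- setdiff(1:2, b_idx)
  ma <- arm_measure(arms[[a_idx]]$outcomes[[outcome]], outcome, r)
  mb <- arm_measure(arms[[b_idx]]$outcomes[[outcome]], outcome, r)
  est <- direct_estimate(
    trial$trial_id, trts[a_idx], trts[b_idx],
    md = ma$mean - mb$mean,
    se = sqrt(ma$sd^2 / ma$n + mb$sd^2 / mb$n),
    source = "measured")
  attr(est, "imputed") <- c(ma$imputed, mb$imputed)
  est
}

#' Preprocessing provenance ledger
#'
#' Per trial x arm x continuous outcome, records whether the analyzed SD was
#' reported or imputed, mirroring the analysis limitation that imputed change
#' SDs compound uncertainty.
#'
#' @param records List of [trial_record()] objects.
#' @param r Correlation estimate used for imputation (optional; rows that
#'   would need it are marked `"unavailable"` when absent).
#' @return A data.frame with one row per trial x arm x continuous outcome and
#'   a `sd_status` column in `{reported, imputed, unavailable}`.
#' @export
preprocessing_ledger <- function(records, r = NULL) {
  rows <- list()
  for (rec in records) {
    for (a in rec$arms) {
      for (oc in names(a$outcomes)) {
        s <- a$outcomes[[oc]]
        if (!inherits(s, "continuous_arm")) next
        status <- tryCatch({
          m <- arm_measure(s, oc, r)
          if (m$imputed) "imputed" else "reported"
        }, error = function(e) "unavailable")
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = rec$trial_id, treatment = a$treatment, outcome = oc,
          sd_status = status, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Read trial-level direct estimates from CSV
#'
#' Schema: `trial_id, outcome, treatment_a, treatment_b, md, cri_lower,
#' cri_upper, provenance`; the SE is reconstructed from the 95\% interval via
#' [se_from_interval()].
#'
#' @param path CSV path (the bundled `direct_estimates.csv` records the
#'   printed base-case contrasts).
#' @return A data.frame with an added `se` column.
#' @export
read_direct_estimates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- c("trial_id", "outcome", "treatment_a", "treatment_b", "md",
           "cri_lower", "cri_upper")
  if (!all(req %in% names(df))) {
    stop("direct-estimates CSV missing required columns", call. = FALSE)
  }
  df$se <- se_from_interval(df$cri_lower, df$cri_upper)
  df
}
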