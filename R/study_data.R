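#' lagnma: Bayesian fixed-effects network meta-analysis of long-acting growth
#' hormones in pediatric growth hormone deficiency
#'
#' Aggregate-data network meta-analysis (NMA) comparing once-weekly long-acting
#' growth hormones (LAGHs: lonapegsomatropin, somapacitan, somatrogon, LB03002)
#' with daily somatropin in treatment-naive pediatric growth hormone deficiency.
#' The package covers the full analysis path: reading arm-level trial summaries,
#' imputing change-from-baseline standard deviations through a pooled
#' baseline/follow-up correlation, building per-outcome evidence networks under
#' explicit feasibility rules, fitting fixed-effects Bayesian models by MCMC,
#' summarising mean differences / odds ratios with 95\% credible intervals,
#' SUCRA treatment rankings, and league-table reporting.
#'
#' @importFrom stats median plogis qlogis qnorm quantile rbinom rnorm runif
#'   sd var setNames
#' @importFrom utils read.csv write.csv combn
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Outcome registry
# ---------------------------------------------------------------------------

#' Outcomes analyzable at the 52-week time point
#'
#' The five outcomes with comparable definitions across the included trials:
#' annualized height velocity (`ahv`, cm/year, value at 52 weeks), change from
#' baseline in height SD score (`height_sds`), change from baseline in weekly
#' average IGF-1 SD score (`igf1_sds`), change from baseline in bone
#' age-to-chronological age ratio (`ba_ca_ratio`), and serious adverse events
#' (`sae`, binary).
#'
#' @return Character vector of outcome ids.
#' @export
lagnma_outcomes <- function() {
  c("ahv", "height_sds", "igf1_sds", "ba_ca_ratio", "sae")
}

#' Kind of likelihood an outcome requires
#'
#' @param outcome Outcome id, see [lagnma_outcomes()].
#' @return `"continuous"` or `"binary"`.
#' @export
outcome_kind <- function(outcome) {
  outcome <- match.arg(outcome, lagnma_outcomes())
  if (outcome == "sae") "binary" else "continuous"
}

#' Ranking direction for an outcome
#'
#' Growth outcomes are ranked higher-is-better; serious adverse events
#' lower-is-better. Bone-age advancement relative to chronological age is a
#' potential harm (premature growth-plate closure) but the benefit/harm framing
#' is debatable, so its direction is configurable with a lower-is-better
#' default.
#'
#' @param outcome Outcome id.
#' @param ba_ca_ratio Direction used for the bone age-to-chronological age
#'   ratio outcome, `"lower"` (default) or `"higher"`.
#' @return `"higher"` or `"lower"`.
#' @export
outcome_direction <- function(outcome, ba_ca_ratio = c("lower", "higher")) {
  outcome <- match.arg(outcome, lagnma_outcomes())
  ba_ca_ratio <- match.arg(ba_ca_ratio)
  switch(outcome,
    ahv = "higher", height_sds = "higher", igf1_sds = "higher",
    ba_ca_ratio = ba_ca_ratio, sae = "lower")
}

# ---------------------------------------------------------------------------
# Treatments
# ---------------------------------------------------------------------------

#' Treatment set for a network
#'
#' @param ids Character vector of unique treatment ids (case-insensitive
#'   tokens; stored lower-case).
#' @param reference Id of the network reference treatment (daily somatropin in
#'   the shipped analyses). Exactly one reference per analysis.
#' @param labels Optional display labels, same length as `ids`.
#' @return A data.frame with columns `id`, `label`, `is_reference`.
#' @export
treatment_set <- function(ids, reference, labels = NULL) {
  ids <- tolower(trimws(as.character(ids)))
  if (anyDuplicated(ids)) {
    stop("treatment ids must be unique within a network", call. = FALSE)
  }
  reference <- tolower(trimws(reference))
  if (length(reference) != 1L || !reference %in% ids) {
    stop("exactly one reference treatment, present in `ids`, is required",
         call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- vapply(ids, default_treatment_label, character(1))
  }
  data.frame(id = ids, label = labels, is_reference = ids == reference,
             stringsAsFactors = FALSE)
}

default_treatment_label <- function(id) {
  labels <- c(
    daily_somatropin  = "Daily somatropin",
    lonapegsomatropin = "Lonapegsomatropin",
    somapacitan       = "Somapacitan",
    somatrogon        = "Somatrogon",
    lb03002           = "LB03002")
  if (id %in% names(labels)) unname(labels[id]) else id
}

# ---------------------------------------------------------------------------
# Arm summaries
# ---------------------------------------------------------------------------

#' Aggregate summary of a continuous outcome in one trial arm
#'
#' At least one of the change-from-baseline pair or the baseline + follow-up
#' pairs must be present; missing quantities are `NA`, never 0.
#'
#' @param n Number of analyzed patients (>= 1).
#' @param baseline_mean,baseline_sd Baseline mean and SD (outcome units).
#' @param followup_mean,followup_sd Follow-up (52-week) mean and SD.
#' @param change_mean,change_sd Change-from-baseline mean and SD.
#' @return An object of class `continuous_arm`.
#' @export
continuous_arm <- function(n, baseline_mean = NA_real_, baseline_sd = NA_real_,
                           followup_mean = NA_real_, followup_sd = NA_real_,
                           change_mean = NA_real_, change_sd = NA_real_) {
  structure(
    list(n = as.numeric(n),
         baseline_mean = as.numeric(baseline_mean),
         baseline_sd = as.numeric(baseline_sd),
         followup_mean = as.numeric(followup_mean),
         followup_sd = as.numeric(followup_sd),
         change_mean = as.numeric(change_mean),
         change_sd = as.numeric(change_sd)),
    class = "continuous_arm")
}

#' Aggregate summary of a binary outcome in one trial arm
#'
#' @param n Number of analyzed patients.
#' @param events Number of patients with at least one event, `0 <= events <= n`.
#' @return An object of class `binary_arm`.
#' @export
binary_arm <- function(n, events) {
  structure(list(n = as.numeric(n), events = as.numeric(events)),
            class = "binary_arm")
}

# ---------------------------------------------------------------------------
# Trial records
# ---------------------------------------------------------------------------

#' One trial's arm-level summaries
#'
#' @param trial_id Trial token (e.g. `"thornton2021"`); case-insensitive.
#' @param week Time point in weeks; the shipped analyses only accept 52.
#' @param arms A list; each element is `list(treatment = <id>, outcomes =
#'   <named list of continuous_arm / binary_arm>)`.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, week, arms) {
  trial_id <- tolower(trimws(trial_id))
  for (a in arms) {
    if (is.null(a$treatment) || !is.list(a$outcomes)) {
      stop("each arm needs a `treatment` id and an `outcomes` list",
           call. = FALSE)
    }
  }
  arms <- lapply(arms, function(a) {
    a$treatment <- tolower(trimws(a$treatment)); a
  })
  structure(list(trial_id = trial_id, week = as.numeric(week), arms = arms),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record> %s (week %g), %d arms\n",
              x$trial_id, x$week, length(x$arms)))
  for (a in x$arms) {
    cat(sprintf("  %-18s outcomes: %s\n", a$treatment,
                paste(names(a$outcomes), collapse = ", ")))
  }
  invisible(x)
}

arm_treatments <- function(rec) {
  vapply(rec$arms, function(a) a$treatment, character(1))
}

#' Validate a trial record against the data-model invariants
#'
#' Reports, never throws: every violated invariant becomes one message naming
#' the trial, arm and field concerned. An empty return means the record is
#' well-formed and analyzable. Checked invariants: at least 2 arms with
#' distinct treatments, outcomes observed at 52 weeks, `n >= 1`, reported SDs
#' strictly positive, events within `[0, n]`, and for continuous outcomes at
#' least one usable pair (change, or baseline + follow-up).
#'
#' @param rec A [trial_record()].
#' @return Character vector of violation messages (empty if none).
#' @export
validate_record <- function(rec) {
  stopifnot(inherits(rec, "trial_record"))
  v <- character(0)
  who <- rec$trial_id
  if (length(rec$arms) < 2L) {
    v <- c(v, sprintf("%s: fewer than 2 arms", who))
  }
  trts <- arm_treatments(rec)
  if (anyDuplicated(trts)) {
    v <- c(v, sprintf("%s: duplicated arm treatment '%s'",
                      who, trts[duplicated(trts)][1]))
  }
  if (!isTRUE(rec$week == 52)) {
    v <- c(v, sprintf(
      "%s: week = %g; only data reported at 52 weeks of treatment are analyzable",
      who, rec$week))
  }
  for (a in rec$arms) {
    for (oc in names(a$outcomes)) {
      s <- a$outcomes[[oc]]
      tag <- sprintf("%s/%s/%s", who, a$treatment, oc)
      if (!is.finite(s$n) || s$n < 1) {
        v <- c(v, sprintf("%s: n must be >= 1 (got %s)", tag, s$n))
      }
      if (inherits(s, "binary_arm")) {
        if (!is.finite(s$events) || s$events < 0 || s$events > s$n) {
          v <- c(v, sprintf("%s: events must lie in [0, n] (got %s)",
                            tag, s$events))
        }
      } else {
        for (f in c("baseline_sd", "followup_sd", "change_sd")) {
          if (!is.na(s[[f]]) && s[[f]] <= 0) {
            v <- c(v, sprintf("%s: %s must be > 0 (got %s)", tag, f, s[[f]]))
          }
        }
        has_change <- !is.na(s$change_mean) && !is.na(s$change_sd)
        has_raw <- !is.na(s$baseline_mean) && !is.na(s$baseline_sd) &&
          !is.na(s$followup_mean) && !is.na(s$followup_sd)
        has_followup <- !is.na(s$followup_mean) && !is.na(s$followup_sd)
        # ahv is analyzed as the 52-week value, so a follow-up pair suffices
        ok <- if (identical(oc, "ahv")) {
          has_followup || has_change
        } else {
          has_change || has_raw
        }
        if (!ok) {
          v <- c(v, sprintf(
            "%s: needs a change pair or baseline+follow-up pairs", tag))
        }
      }
    }
  }
  v
}

# ---------------------------------------------------------------------------
# Scenarios
# ---------------------------------------------------------------------------

#' Analytic scenario: which trials enter the network
#'
#' The base case comprises the three trials judged similar enough in design and
#' population (Thornton, Deal, Miller). Sensitivity analysis 1 adds the
#' LB03002 trial (Khadilkar); sensitivity analysis 2 adds the Japanese
#' somatrogon trial (Horikawa).
#'
#' @param name `"base"`, `"sa1"`, `"sa2"`, or `"custom"`.
#' @param trial_ids Required for `"custom"`; ignored otherwise.
#' @return An object of class `scenario` with fields `name` and `trial_ids`.
#' @export
scenario <- function(name = c("base", "sa1", "sa2", "custom"),
                     trial_ids = NULL) {
  name <- match.arg(name)
  base <- c("thornton2021", "deal2022", "miller2022")
  ids <- switch(name,
    base = base,
    sa1 = c(base, "khadilkar2007"),
    sa2 = c(base, "horikawa2022"),
    custom = {
      if (is.null(trial_ids) || length(trial_ids) == 0) {
        stop("a custom scenario requires `trial_ids`", call. = FALSE)
      }
      tolower(trimws(trial_ids))
    })
  structure(list(name = name, trial_ids = sort(unique(ids))),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s: {%s}\n", x$name,
              paste(x$trial_ids, collapse = ", ")))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CSV input schema
# ---------------------------------------------------------------------------

trials_schema <- c("trial_id", "week", "treatment", "outcome", "n",
                   "baseline_mean", "baseline_sd", "followup_mean",
                   "followup_sd", "change_mean", "change_sd", "events")

num_cols <- setdiff(trials_schema, c("trial_id", "treatment", "outcome"))

#' Read arm-level trial summaries from CSV
#'
#' The schema is one row per trial x arm x outcome, comma-separated, UTF-8,
#' "." decimal, with header `trial_id, week, treatment, outcome, n,
#' baseline_mean, baseline_sd, followup_mean, followup_sd, change_mean,
#' change_sd, events`. Empty cells are missing values (never zeros); extra
#' columns (e.g. a `provenance` bookkeeping column in the shipped fixtures)
#' are carried along but ignored by the analysis.
#'
#' @param path Path to the CSV file.
#' @return A list of [trial_record()] objects, one per distinct `trial_id`,
#'   in first-appearance order.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, colClasses = "character", check.names = TRUE,
                 fileEncoding = "UTF-8")
  missing_cols <- setdiff(trials_schema, names(df))
  if (length(missing_cols)) {
    stop("CSV header missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  for (cc in num_cols) {
    raw <- trimws(df[[cc]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(nzchar(raw) & is.na(val))
    if (length(bad)) {
      stop(sprintf("malformed value '%s' in column '%s' at data row %d of %s",
                   raw[bad[1]], cc, bad[1], basename(path)), call. = FALSE)
    }
    val[!nzchar(raw)] <- NA_real_
    df[[cc]] <- val
  }
  df$trial_id <- tolower(trimws(df$trial_id))
  df$treatment <- tolower(trimws(df$treatment))
  df$outcome <- tolower(trimws(df$outcome))
  bad_oc <- setdiff(unique(df$outcome), lagnma_outcomes())
  if (length(bad_oc)) {
    stop("unknown outcome(s): ", paste(bad_oc, collapse = ", "), call. = FALSE)
  }
  key <- paste(df$trial_id, df$treatment, df$outcome, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (trial, treatment, outcome) row: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  records <- list()
  for (tid in unique(df$trial_id)) {
    sub <- df[df$trial_id == tid, , drop = FALSE]
    weeks <- unique(sub$week)
    if (length(weeks) != 1L) {
      stop(sprintf("trial '%s' has inconsistent week values", tid),
           call. = FALSE)
    }
    arms <- list()
    for (trt in unique(sub$treatment)) {
      asub <- sub[sub$treatment == trt, , drop = FALSE]
      outcomes <- list()
      for (i in seq_len(nrow(asub))) {
        row <- asub[i, ]
        s <- if (outcome_kind(row$outcome) == "binary") {
          binary_arm(n = row$n, events = row$events)
        } else {
          continuous_arm(n = row$n,
                         baseline_mean = row$baseline_mean,
                         baseline_sd = row$baseline_sd,
                         followup_mean = row$followup_mean,
                         followup_sd = row$followup_sd,
                         change_mean = row$change_mean,
                         change_sd = row$change_sd)
        }
        outcomes[[row$outcome]] <- s
      }
      arms[[length(arms) + 1L]] <- list(treatment = trt, outcomes = outcomes)
    }
    rec <- trial_record(tid, weeks, arms)
    bad <- grep("events must lie", validate_record(rec), value = TRUE)
    if (length(bad)) stop(bad[1], call. = FALSE)
    records[[length(records) + 1L]] <- rec
  }
  records
}

# numbers formatted so that read.csv() recovers them bit-identically
fmt_num <- function(x) {
  s <- as.character(x)
  chk <- suppressWarnings(as.numeric(s))
  bad <- !is.na(x) & (is.na(chk) | chk != x)
  s[bad] <- sprintf("%.17g", x[bad])
  s[is.na(x)] <- ""
  s
}

#' Write trial records to the CSV input schema
#'
#' Inverse of [read_trials()]; numeric cells survive a round trip
#' bit-identically and missing values become empty cells.
#'
#' @param records List of [trial_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(records, path) {
  rows <- list()
  for (rec in records) {
    for (a in rec$arms) {
      for (oc in names(a$outcomes)) {
        s <- a$outcomes[[oc]]
        rows[[length(rows) + 1L]] <- data.frame(
          trial_id = rec$trial_id, week = rec$week, treatment = a$treatment,
          outcome = oc, n = s$n,
          baseline_mean = s$baseline_mean %||% NA_real_,
          baseline_sd = s$baseline_sd %||% NA_real_,
          followup_mean = s$followup_mean %||% NA_real_,
          followup_sd = s$followup_sd %||% NA_real_,
          change_mean = s$change_mean %||% NA_real_,
          change_sd = s$change_sd %||% NA_real_,
          events = if (inherits(s, "binary_arm")) s$events else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  for (cc in num_cols) df[[cc]] <- fmt_num(df[[cc]])
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a bundled fixture file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path, or a vector of file names.
#' @export
lagnma_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "lagnma")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no bundled fixture named ", file, call. = FALSE)
  path
}
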