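# Evidence-network construction and feasibility rules.

# classed conditions so callers (and the pipeline) can distinguish failures
feasibility_error <- function(message) {
  structure(class = c("lagnma_feasibility_error", "error", "condition"),
            list(message = message, call = NULL))
}

convergence_error <- function(message) {
  structure(class = c("lagnma_convergence_error", "error", "condition"),
            list(message = message, call = NULL))
}

validation_error <- function(message) {
  structure(class = c("lagnma_validation_error", "error", "condition"),
            list(message = message, call = NULL))
}

#' Build the per-outcome evidence network for a scenario
#'
#' Includes only trials that (a) belong to the scenario, (b) were observed at
#' 52 weeks, and (c) report the outcome in at least two arms. The feasibility
#' rule requires at least 2 contributing studies per outcome and scenario;
#' fewer raises a feasibility error naming both. The result is independent of
#' the ordering of `trials`.
#'
#' @param trials List of [trial_record()] objects.
#' @param outcome Outcome id, see [lagnma_outcomes()].
#' @param scenario A [scenario()].
#' @param reference Network reference treatment id (default daily somatropin).
#' @param min_studies Feasibility threshold (default 2 studies).
#' @return An object of class `evidence_network`: treatments as nodes, one
#'   edge per trial arm pair, plus the contributing trial records.
#' @export
build_network <- function(trials, outcome, scenario,
                          reference = "daily_somatropin", min_studies = 2L) {
  stopifnot(inherits(scenario, "scenario"))
  outcome <- match.arg(outcome, lagnma_outcomes())
  reference <- tolower(reference)
  keep <- list()
  for (rec in trials) {
    if (!rec$trial_id %in% scenario$trial_ids) next
    if (!isTRUE(rec$week == 52)) next
    has <- vapply(rec$arms, function(a) outcome %in% names(a$outcomes),
                  logical(1))
    if (sum(has) < 2L) next
    rec$arms <- rec$arms[has]
    keep[[rec$trial_id]] <- rec
  }
  keep <- keep[order(names(keep))]
  if (length(keep) < min_studies) {
    stop(feasibility_error(sprintf(
      "outcome '%s' in scenario '%s' is reported by %d stud%s at 52 weeks; at least %d are required",
      outcome, scenario$name, length(keep),
      if (length(keep) == 1) "y" else "ies", min_studies)))
  }
  edges <- list()
  for (rec in keep) {
    trts <- sort(arm_treatments(rec))
    pairs <- combn(trts, 2)
    for (j in seq_len(ncol(pairs))) {
      edges[[length(edges) + 1L]] <- data.frame(
        trial_id = rec$trial_id, treatment_a = pairs[1, j],
        treatment_b = pairs[2, j], stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, edges)
  nodes <- sort(unique(c(edges$treatment_a, edges$treatment_b)))
  if (reference %in% nodes) {
    nodes <- c(reference, setdiff(nodes, reference))
  }
  structure(list(outcome = outcome, scenario = scenario,
                 treatments = nodes, edges = edges, reference = reference,
                 trials = unname(keep)),
            class = "evidence_network")
}

#' @export
print.evidence_network <- function(x, ...) {
  comp <- connected_components(x)
  cat(sprintf(
    "<evidence_network> outcome '%s', scenario '%s': %d treatments, %d edges (%d trial(s)), %s\n",
    x$outcome, x$scenario$name, length(x$treatments), nrow(x$edges),
    length(x$trials),
    if (length(comp) == 1L) "connected" else
      sprintf("%d components", length(comp))))
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s: %s -- %s\n", e$trial_id, e$treatment_a, e$treatment_b))
  }
  invisible(x)
}

#' Connected components of an evidence network
#'
#' Analysis proceeds only when the network forms a single component; this
#' partitions the treatment nodes by trial-edge connectivity.
#'
#' @param net An [build_network()] result (an empty network gives `list()`).
#' @return A list of character vectors of treatment ids, one per component.
#' @export
connected_components <- function(net) {
  stopifnot(inherits(net, "evidence_network"))
  if (length(net$treatments) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    net$edges[, c("treatment_a", "treatment_b")], directed = FALSE,
    vertices = data.frame(name = net$treatments))
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership) |>
    lapply(sort) |> unname()
}

is_connected_network <- function(net) {
  length(connected_components(net)) == 1L
}

#' Export a network as an edge-list CSV
#'
#' @param net An `evidence_network`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_network_csv <- function(net, path) {
  write.csv(net$edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Render a network as a DOT graph description
#'
#' Produces a Graphviz DOT string mirroring the evidence-network diagram:
#' treatments as nodes (reference boxed), one labelled edge per trial.
#'
#' @param net An `evidence_network`.
#' @return A character scalar of DOT source.
#' @export
network_dot <- function(net) {
  lines <- c(sprintf("graph \"%s_%s\" {", net$outcome, net$scenario$name))
  for (t in net$treatments) {
    shape <- if (identical(t, net$reference)) "box" else "ellipse"
    lines <- c(lines, sprintf("  \"%s\" [shape=%s];", t, shape))
  }
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    lines <- c(lines, sprintf("  \"%s\" -- \"%s\" [label=\"%s\"];",
                              e$treatment_a, e$treatment_b, e$trial_id))
  }
  paste(c(lines, "}"), collapse = "\n")
}
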