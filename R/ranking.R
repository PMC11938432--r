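# SUCRA rankings from posterior draws.

#' Per-draw treatment ranks
#'
#' Within each retained draw the treatments are ranked by their basic
#' parameter: rank 1 is the largest `d` for higher-is-better outcomes and the
#' smallest for lower-is-better ones. Exact ties (measure-zero under the
#' continuous posterior) are broken deterministically by treatment id order,
#' never by rank averaging.
#'
#' @param draws An `nma_draws` object.
#' @param direction `"higher"` or `"lower"` (better).
#' @return Integer matrix, retained draws x treatments, entries in `1..K`.
#' @export
rank_draws <- function(draws, direction = c("higher", "lower")) {
  stopifnot(inherits(draws, "nma_draws"))
  direction <- match.arg(direction)
  d <- draws$d[, sort(colnames(draws$d)), drop = FALSE] # id order for ties
  key <- if (direction == "higher") -d else d
  ranks <- t(apply(key, 1, rank, ties.method = "first"))
  storage.mode(ranks) <- "integer"
  ranks
}

#' Rank-probability matrix
#'
#' @param ranks Matrix from [rank_draws()].
#' @return K x K matrix; entry (k, j) is the probability treatment k has
#'   rank j. Rows and columns each sum to 1.
#' @export
rank_probabilities <- function(ranks) {
  K <- ncol(ranks)
  probs <- vapply(seq_len(K), function(j) colMeans(ranks == j),
                  numeric(K))
  dimnames(probs) <- list(colnames(ranks), paste0("rank", seq_len(K)))
  probs
}

valid_rank_probs <- function(rank_probs, tol = 1e-9) {
  all(abs(rowSums(rank_probs) - 1) < tol) &&
    all(abs(colSums(rank_probs) - 1) < tol) && all(rank_probs >= -tol)
}

#' SUCRA scores from a rank-probability matrix
#'
#' The surface under the cumulative ranking curve for treatment k is
#' `sucra_k = (1 / (K - 1)) * sum_{j=1}^{K-1} P(rank_k <= j)`: 1 (100\%) for a
#' treatment certain to rank first, 0 for one certain to rank last, and the
#' scores always average 0.5 across treatments.
#'
#' @param rank_probs K x K matrix from [rank_probabilities()], `K >= 2`.
#' @return Named numeric vector of scores in `[0, 1]`.
#' @export
sucra <- function(rank_probs) {
  rank_probs <- as.matrix(rank_probs)
  K <- ncol(rank_probs)
  if (K < 2 || nrow(rank_probs) != K) {
    stop("rank_probs must be a square matrix with K >= 2", call. = FALSE)
  }
  if (!valid_rank_probs(rank_probs)) {
    stop("rank_probs rows and columns must each sum to 1", call. = FALSE)
  }
  cum <- t(apply(rank_probs, 1, cumsum))
  scores <- rowSums(cum[, seq_len(K - 1), drop = FALSE]) / (K - 1)
  setNames(as.numeric(scores), rownames(rank_probs))
}

#' Probability of being the best treatment
#'
#' @param rank_probs Matrix from [rank_probabilities()].
#' @return Named vector: probability of rank 1 per treatment (sums to 1).
#' @export
probability_best <- function(rank_probs) {
  rank_probs <- as.matrix(rank_probs)
  if (!valid_rank_probs(rank_probs)) {
    stop("rank_probs rows and columns must each sum to 1", call. = FALSE)
  }
  setNames(rank_probs[, 1], rownames(rank_probs))
}

#' Full ranking result for an outcome
#'
#' Convenience wrapper: per-draw ranks, rank probabilities, SUCRA,
#' probability-best and expected rank, with the ranking direction resolved
#' from the outcome (see [outcome_direction()]) unless given explicitly.
#'
#' @param draws An `nma_draws` object.
#' @param direction `"higher"`/`"lower"`; default derived from the outcome.
#' @param ... Passed to [outcome_direction()] (e.g. `ba_ca_ratio =`).
#' @return An object of class `ranking_result`.
#' @export
rank_treatments <- function(draws, direction = NULL, ...) {
  stopifnot(inherits(draws, "nma_draws"))
  if (is.null(direction)) {
    if (is.null(draws$outcome)) {
      stop("no outcome on the draws; supply `direction`", call. = FALSE)
    }
    direction <- outcome_direction(draws$outcome, ...)
  }
  ranks <- rank_draws(draws, direction)
  probs <- rank_probabilities(ranks)
  structure(list(outcome = draws$outcome, direction = direction,
                 rank_probs = probs, sucra = sucra(probs),
                 p_best = probability_best(probs),
                 expected_rank = setNames(
                   as.numeric(probs %*% seq_len(ncol(probs))),
                   rownames(probs))),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> outcome '%s' (%s is better)\n",
              x$outcome %||% "?", x$direction))
  ord <- order(-x$sucra)
  for (k in ord) {
    cat(sprintf("  %-18s SUCRA %3.0f%%  P(best) %4.2f  E[rank] %.2f\n",
                names(x$sucra)[k], 100 * x$sucra[k], x$p_best[k],
                x$expected_rank[k]))
  }
  invisible(x)
}

#' Export a ranking table as CSV
#'
#' One row per treatment with probability-best, SUCRA (percent) and expected
#' rank, sorted by SUCRA.
#'
#' @param ranking A [rank_treatments()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  ord <- order(-ranking$sucra)
  df <- data.frame(treatment = names(ranking$sucra)[ord],
                   p_best = unname(ranking$p_best[ord]),
                   sucra_pct = unname(100 * ranking$sucra[ord]),
                   expected_rank = unname(ranking$expected_rank[ord]),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
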