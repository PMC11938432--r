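# Fixed-effects Bayesian network meta-analysis engine.
#
# Arm-based generalized linear models in the NICE DSU style: each trial i
# carries a baseline nuisance parameter mu_i, and each non-reference treatment
# k a basic parameter d_k (relative effect vs the network reference, which is
# fixed at 0). Under consistency the linear predictor of arm (i, k) is
#   theta_ik = mu_i + d_{t_ik} - d_{t_i1},
# with t_i1 the trial's own baseline treatment. Continuous outcomes use an
# identity-link normal likelihood on the arm summary (known SE); binary
# outcomes an exact binomial likelihood with logit link.

#' Model specification for a fixed-effects NMA run
#'
#' Priors are vague normals in the NICE DSU convention, `Normal(0, 100^2)` on
#' the model scale for both basic parameters and trial baselines, and are
#' configurable. Only fixed treatment effects are supported: the evidence
#' networks this package targets are too sparse for heterogeneity estimation.
#'
#' @param outcome_kind `"continuous"` (mean differences) or `"binary"`
#'   (odds ratios, modelled on the log-odds scale).
#' @param prior_sd_d Prior SD of the basic parameters (outcome units or
#'   log-odds), > 0.
#' @param prior_sd_mu Prior SD of the trial baselines, > 0.
#' @param chains Number of MCMC chains (>= 2, for split-chain diagnostics).
#' @param iterations Iterations per chain, including burn-in.
#' @param burn_in Discarded iterations per chain, < `iterations`.
#' @param seed Integer seed; identical spec + seed gives bit-identical draws.
#' @return An object of class `nma_model_spec`.
#' @export
nma_model_spec <- function(outcome_kind = c("continuous", "binary"),
                           prior_sd_d = 100, prior_sd_mu = 100,
                           chains = 4L, iterations = 20000L, burn_in = 5000L,
                           seed = 1L) {
  outcome_kind <- match.arg(outcome_kind)
  chains <- as.integer(chains)
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  if (chains < 2L) stop("at least 2 chains are required", call. = FALSE)
  if (burn_in >= iterations) {
    stop("burn_in must be smaller than iterations", call. = FALSE)
  }
  if (prior_sd_d <= 0 || prior_sd_mu <= 0) {
    stop("prior SDs must be > 0", call. = FALSE)
  }
  structure(list(outcome_kind = outcome_kind, effects = "fixed",
                 prior_sd_d = prior_sd_d, prior_sd_mu = prior_sd_mu,
                 chains = chains, iterations = iterations, burn_in = burn_in,
                 seed = as.integer(seed)),
            class = "nma_model_spec")
}

#' @export
print.nma_model_spec <- function(x, ...) {
  cat(sprintf(
    "<nma_model_spec> %s, fixed effects; priors N(0, %g^2)/N(0, %g^2); %d chains x %d iter (%d burn-in); seed %d\n",
    x$outcome_kind, x$prior_sd_d, x$prior_sd_mu, x$chains, x$iterations,
    x$burn_in, x$seed))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Design assembly
# ---------------------------------------------------------------------------

# One row per arm: linear-predictor design theta = X beta, where beta stacks
# the non-reference basic parameters then the trial baselines. The trial
# baseline treatment is the arm whose treatment comes first in the network's
# treatment ordering (the reference itself in the shipped star networks).
nma_design <- function(net) {
  trts <- net$treatments
  d_names <- setdiff(trts, net$reference)
  trials <- vapply(net$trials, function(tr) tr$trial_id, character(1))
  rows <- list()
  for (i in seq_along(net$trials)) {
    rec <- net$trials[[i]]
    atrts <- arm_treatments(rec)
    base_trt <- atrts[which.min(match(atrts, trts))]
    for (k in seq_along(rec$arms)) {
      rows[[length(rows) + 1L]] <- list(
        trial = i, treatment = atrts[k], base = base_trt, arm = k)
    }
  }
  A <- length(rows)
  P <- length(d_names) + length(trials)
  X <- matrix(0, A, P,
              dimnames = list(NULL, c(paste0("d_", d_names),
                                      paste0("mu_", trials))))
  for (a in seq_len(A)) {
    r <- rows[[a]]
    X[a, length(d_names) + r$trial] <- 1
    if (r$treatment %in% d_names) X[a, paste0("d_", r$treatment)] <- X[a, paste0("d_", r$treatment)] + 1
    if (r$base %in% d_names) X[a, paste0("d_", r$base)] <- X[a, paste0("d_", r$base)] - 1
  }
  list(X = X, rows = rows, d_names = d_names, trial_ids = trials)
}

# ---------------------------------------------------------------------------
# Posterior container
# ---------------------------------------------------------------------------

new_nma_draws <- function(sims, design, net, spec, scale) {
  # sims: array [kept iterations, chains, parameters]
  K <- length(net$treatments)
  keep <- dim(sims)[1]; C <- dim(sims)[2]
  nd <- length(design$d_names)
  d_flat <- matrix(0, keep * C, K, dimnames = list(NULL, net$treatments))
  for (j in seq_len(nd)) {
    d_flat[, design$d_names[j]] <- as.vector(sims[, , j])
  }
  mu_flat <- matrix(NA_real_, keep * C, length(design$trial_ids),
                    dimnames = list(NULL, design$trial_ids))
  for (j in seq_along(design$trial_ids)) {
    mu_flat[, j] <- as.vector(sims[, , nd + j])
  }
  diag_df <- mcmc_diagnostics(sims, dimnames(sims)[[3]])
  structure(list(d = d_flat, mu = mu_flat, sims = sims,
                 treatments = net$treatments, reference = net$reference,
                 outcome = net$outcome, scale = scale, spec = spec,
                 diagnostics = diag_df),
            class = "nma_draws")
}

#' @export
print.nma_draws <- function(x, ...) {
  cat(sprintf(
    "<nma_draws> %s scale, %d retained draws (%d chains), reference '%s'\n",
    x$scale, nrow(x$d), x$spec$chains, x$reference))
  cat("  max split-Rhat:", format(max(x$diagnostics$rhat), digits = 4),
      " min ESS:", format(min(x$diagnostics$ess), digits = 5), "\n")
  invisible(x)
}

# split-chain potential scale reduction (each chain halved, then the usual
# between/within variance ratio) plus coda effective sample sizes
mcmc_diagnostics <- function(sims, par_names) {
  keep <- dim(sims)[1]; C <- dim(sims)[2]; P <- dim(sims)[3]
  half <- floor(keep / 2)
  rhat <- ess <- numeric(P)
  for (j in seq_len(P)) {
    m <- sims[, , j, drop = FALSE][, , 1]
    splits <- cbind(m[seq_len(half), , drop = FALSE],
                    m[(keep - half + 1):keep, , drop = FALSE])
    mns <- colMeans(splits)
    vars <- apply(splits, 2, var)
    W <- mean(vars)
    B <- half * var(mns)
    vhat <- (half - 1) / half * W + B / half
    rhat[j] <- if (W > 0) sqrt(vhat / W) else 1
    ess[j] <- sum(vapply(seq_len(C), function(cc)
      as.numeric(coda::effectiveSize(coda::mcmc(m[, cc]))), numeric(1)))
  }
  data.frame(parameter = par_names, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}

check_convergence <- function(draws) {
  dg <- draws$diagnostics
  is_d <- startsWith(dg$parameter, "d_")
  bad <- is_d & (dg$rhat > 1.05 | dg$ess < 400)
  if (any(bad)) {
    stop(convergence_error(sprintf(
      "MCMC did not converge: %s (split-Rhat must be <= 1.05 and ESS >= 400 for every basic parameter)",
      paste(sprintf("%s [Rhat %.3f, ESS %.0f]", dg$parameter[bad],
                    dg$rhat[bad], dg$ess[bad]), collapse = "; "))))
  }
  invisible(draws)
}

# ---------------------------------------------------------------------------
# Continuous model: conjugate Gibbs
# ---------------------------------------------------------------------------

#' Fit the fixed-effects NMA for a continuous outcome
#'
#' Arm-based identity-link normal likelihood: the per-arm analysis measure
#' `y_ik` (52-week value for annualized height velocity, change from baseline
#' otherwise) is modelled as `y_ik ~ Normal(mu_i + d_{t_ik} - d_{t_i1},
#' se_ik^2)` with `se_ik = sd_ik / sqrt(n_ik)` treated as known. With normal
#' priors this model is fully conjugate: the joint posterior of the basic
#' parameters and trial baselines is multivariate Gaussian in closed form, so
#' the sampler draws the whole parameter block jointly per iteration (exact,
#' independent posterior draws; a one-block Gibbs sampler). Chain structure
#' and diagnostics are retained so continuous and binary fits share one
#' contract, and parameter-at-a-time mixing pathologies cannot arise.
#'
#' @param net A connected [build_network()] result containing the reference.
#' @param spec An [nma_model_spec()] with `outcome_kind = "continuous"`.
#' @param correlation Optional correlation ([estimate_correlation()] result or
#'   number) for change-SD imputation where arms lack a reported change SD.
#' @param check If `TRUE` (default), error on failed convergence diagnostics
#'   rather than returning a result silently.
#' @return An object of class `nma_draws`.
#' @export
fit_continuous <- function(net, spec = nma_model_spec("continuous"),
                           correlation = NULL, check = TRUE) {
  stopifnot(inherits(net, "evidence_network"),
            inherits(spec, "nma_model_spec"))
  if (spec$outcome_kind != "continuous") {
    stop("spec$outcome_kind must be 'continuous'", call. = FALSE)
  }
  if (!is_connected_network(net)) {
    stop(feasibility_error(sprintf(
      "evidence network for outcome '%s' is disconnected; analysis requires a single component",
      net$outcome)))
  }
  des <- nma_design(net)
  y <- se <- numeric(length(des$rows))
  for (a in seq_along(des$rows)) {
    r <- des$rows[a][[1]]
    s <- net$trials[[r$trial]]$arms[[r$arm]]$outcomes[[net$outcome]]
    m <- arm_measure(s, net$outcome, correlation)
    y[a] <- m$mean
    se[a] <- m$sd / sqrt(m$n)
  }
  if (any(!is.finite(se) | se <= 0)) {
    stop("non-positive or missing arm standard error", call. = FALSE)
  }
  X <- des$X
  P <- ncol(X); C <- spec$chains
  nd <- length(des$d_names)
  w <- 1 / se^2
  prior_prec <- c(rep(1 / spec$prior_sd_d^2, nd),
                  rep(1 / spec$prior_sd_mu^2, P - nd))
  # joint Gaussian posterior: precision Lambda, mean m
  XtW <- t(X * w)
  Lambda <- XtW %*% X + diag(prior_prec, P)
  U <- chol(Lambda)
  m <- drop(backsolve(U, backsolve(U, XtW %*% y, transpose = TRUE)))
  set.seed(spec$seed)
  keep <- spec$iterations - spec$burn_in
  N <- keep * C
  # beta ~ N(m, Lambda^-1): beta = m + U^-1 z, drawn for all chains at once
  Z <- matrix(rnorm(P * N), P, N)
  B <- m + backsolve(U, Z)
  sims <- array(NA_real_, c(keep, C, P),
                dimnames = list(NULL, NULL, colnames(X)))
  for (j in seq_len(P)) sims[, , j] <- matrix(B[j, ], keep, C)
  draws <- new_nma_draws(sims, des, net, spec, scale = "md")
  if (check) check_convergence(draws)
  draws
}

# ---------------------------------------------------------------------------
# Binary model: adaptive random-walk Metropolis within Gibbs
# ---------------------------------------------------------------------------

#' Fit the fixed-effects NMA for a binary outcome
#'
#' Exact binomial likelihood with logit link: `r_ik ~ Binomial(n_ik, p_ik)`,
#' `logit(p_ik) = mu_i + d_{t_ik} - d_{t_i1}`. No continuity correction is
#' applied; zero-event arms are handled by the likelihood itself, which stays
#' proper under the priors. Sampling is single-site random-walk Metropolis
#' within Gibbs with per-parameter step sizes adapted towards a 0.44
#' acceptance rate during burn-in only.
#'
#' @inheritParams fit_continuous
#' @param spec An [nma_model_spec()] with `outcome_kind = "binary"`.
#' @return An object of class `nma_draws` with `d` on the log-odds scale.
#' @export
fit_binary <- function(net, spec = nma_model_spec("binary"), check = TRUE) {
  stopifnot(inherits(net, "evidence_network"),
            inherits(spec, "nma_model_spec"))
  if (spec$outcome_kind != "binary") {
    stop("spec$outcome_kind must be 'binary'", call. = FALSE)
  }
  if (!is_connected_network(net)) {
    stop(feasibility_error(sprintf(
      "evidence network for outcome '%s' is disconnected; analysis requires a single component",
      net$outcome)))
  }
  des <- nma_design(net)
  r_ev <- n_ev <- numeric(length(des$rows))
  for (a in seq_along(des$rows)) {
    rw <- des$rows[a][[1]]
    s <- net$trials[[rw$trial]]$arms[[rw$arm]]$outcomes[[net$outcome]]
    if (!inherits(s, "binary_arm")) {
      stop("outcome '", net$outcome, "' is not binary in all arms",
           call. = FALSE)
    }
    if (s$events > s$n) stop("events exceed n", call. = FALSE)
    r_ev[a] <- s$events; n_ev[a] <- s$n
  }
  X <- des$X
  P <- ncol(X); C <- spec$chains
  nd <- length(des$d_names)
  prior_prec <- c(rep(1 / spec$prior_sd_d^2, nd),
                  rep(1 / spec$prior_sd_mu^2, P - nd))
  set.seed(spec$seed)
  beta <- matrix(rnorm(P * C, 0, 1), P, C)
  for (i in seq_along(des$trial_ids)) {
    base_a <- which(X[, nd + i] == 1)[1]
    emp <- qlogis((r_ev[base_a] + 0.5) / (n_ev[base_a] + 1))
    beta[nd + i, ] <- emp + rnorm(C, 0, 1)
  }
  theta <- X %*% beta
  # binomial log-likelihood per arm (constants dropped)
  arm_ll <- function(th, idx) {
    r_ev[idx] * th - n_ev[idx] * log1p(exp(th))
  }
  step <- rep(0.5, P)
  acc <- att <- rep(0, P)
  keep <- spec$iterations - spec$burn_in
  sims <- array(NA_real_, c(keep, C, P),
                dimnames = list(NULL, NULL, colnames(X)))
  nz_list <- lapply(seq_len(P), function(j) which(X[, j] != 0))
  for (it in seq_len(spec$iterations)) {
    for (j in seq_len(P)) {
      nz <- nz_list[[j]]
      prop <- beta[j, ] + step[j] * rnorm(C)
      th_old <- theta[nz, , drop = FALSE]
      th_new <- th_old + outer(X[nz, j], prop - beta[j, ])
      ll_old <- colSums(arm_ll(th_old, nz))
      ll_new <- colSums(arm_ll(th_new, nz))
      lp_old <- -0.5 * prior_prec[j] * beta[j, ]^2
      lp_new <- -0.5 * prior_prec[j] * prop^2
      accept <- log(runif(C)) < (ll_new + lp_new - ll_old - lp_old)
      if (any(accept)) {
        theta[nz, accept] <- th_new[, accept, drop = FALSE]
        beta[j, accept] <- prop[accept]
      }
      att[j] <- att[j] + C
      acc[j] <- acc[j] + sum(accept)
    }
    if (it <= spec$burn_in && it %% 50L == 0L) {
      rate <- acc / pmax(att, 1)
      step <- pmin(10, pmax(1e-3, step * exp(rate - 0.44)))
      acc[] <- att[] <- 0
    }
    if (it > spec$burn_in) sims[it - spec$burn_in, , ] <- t(beta)
  }
  draws <- new_nma_draws(sims, des, net, spec, scale = "logor")
  if (check) check_convergence(draws)
  draws
}

# ---------------------------------------------------------------------------
# Posterior summaries
# ---------------------------------------------------------------------------

#' Per-draw posterior samples of a treatment contrast
#'
#' @param draws An `nma_draws` object.
#' @param treatment_a,treatment_b Treatment ids; the contrast is A minus B on
#'   the model scale (mean difference or log-odds ratio).
#' @return Numeric vector, one value per retained draw.
#' @export
contrast_draws <- function(draws, treatment_a, treatment_b) {
  stopifnot(inherits(draws, "nma_draws"))
  for (t in c(treatment_a, treatment_b)) {
    if (!t %in% draws$treatments) {
      stop("unknown treatment: ", t, call. = FALSE)
    }
  }
  draws$d[, treatment_a] - draws$d[, treatment_b]
}

#' Summarize all pairwise contrasts from posterior draws
#'
#' For every ordered pair (A, B) the per-draw contrast `d_A - d_B` is formed
#' (and exponentiated for the odds-ratio scale); the point estimate is the
#' posterior median and the 95\% credible interval the 2.5th/97.5th
#' percentiles. Antisymmetry holds draw by draw: MD(A,B) = -MD(B,A) and
#' OR(A,B) = 1/OR(B,A).
#'
#' @param draws An `nma_draws` object.
#' @param scale `"md"` for mean differences or `"or"` for odds ratios;
#'   defaults to the natural scale of the fitted model.
#' @return A data.frame of class `effect_estimates` with one row per ordered
#'   contrast: `treatment_a`, `treatment_b`, `scale`, `point`, `cri_lower`,
#'   `cri_upper`.
#' @export
summarize_effects <- function(draws, scale = NULL) {
  stopifnot(inherits(draws, "nma_draws"))
  if (is.null(scale)) scale <- if (draws$scale == "logor") "or" else "md"
  scale <- match.arg(scale, c("md", "or"))
  if (scale == "or" && draws$scale != "logor") {
    stop("odds-ratio summaries require a binary-outcome fit", call. = FALSE)
  }
  trts <- draws$treatments
  out <- list()
  for (a in trts) for (b in trts) {
    if (a == b) next
    cd <- contrast_draws(draws, a, b)
    if (scale == "or") cd <- exp(cd)
    qs <- unname(quantile(cd, c(0.025, 0.975)))
    out[[length(out) + 1L]] <- data.frame(
      treatment_a = a, treatment_b = b, scale = scale,
      point = median(cd), cri_lower = qs[1], cri_upper = qs[2],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("effect_estimates", "data.frame")
  res
}

#' Export retained draws as a plain CSV
#'
#' One row per retained draw with the basic parameters (all treatments,
#' reference column identically 0) and trial baselines.
#'
#' @param draws An `nma_draws` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(draws, path) {
  df <- cbind(as.data.frame(draws$d),
              setNames(as.data.frame(draws$mu),
                       paste0("mu_", colnames(draws$mu))))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rebuild an `nma_draws` object from an exported draws CSV
#'
#' Supports regenerating league tables and summaries from archived runs.
#'
#' @param path CSV written by [write_draws_csv()].
#' @param reference Reference treatment id.
#' @param scale `"md"` or `"logor"`.
#' @param outcome Optional outcome id carried on the result.
#' @return A minimal `nma_draws` object (no diagnostics).
#' @export
read_draws_csv <- function(path, reference, scale = c("md", "logor"),
                           outcome = NULL) {
  scale <- match.arg(scale)
  df <- read.csv(path, stringsAsFactors = FALSE)
  mu_cols <- grep("^mu_", names(df), value = TRUE)
  trts <- setdiff(names(df), mu_cols)
  structure(list(d = as.matrix(df[, trts, drop = FALSE]),
                 mu = as.matrix(df[, mu_cols, drop = FALSE]),
                 sims = NULL, treatments = trts,
                 reference = tolower(reference), outcome = outcome,
                 scale = scale, spec = NULL, diagnostics = NULL),
            class = "nma_draws")
}

# ---------------------------------------------------------------------------
# Frequentist oracle
# ---------------------------------------------------------------------------

#' Inverse-variance frequentist network estimator (validation oracle)
#'
#' Weighted-least-squares solution for the basic parameters given independent
#' normal trial-level direct estimates. For vague priors the Bayesian
#' posterior of the fixed-effects normal model coincides with this estimator,
#' which makes it an independent check of the MCMC engine; in a star network
#' it reduces to `indirect(A, B) = direct(A, ref) - direct(B, ref)` with
#' variances adding.
#'
#' @param net An `evidence_network` (supplies treatments and reference).
#' @param direct_estimates List of [direct_estimate()] objects or a data.frame
#'   with columns `treatment_a`, `treatment_b`, `md`, `se`.
#' @return A data.frame with one row per ordered contrast: `point`, `se`,
#'   `lower`, `upper` (95\% Wald interval).
#' @export
frequentist_oracle <- function(net, direct_estimates) {
  trts <- net$treatments
  ref <- net$reference
  d_names <- setdiff(trts, ref)
  if (inherits(direct_estimates, "direct_estimate")) {
    direct_estimates <- list(direct_estimates)
  }
  if (is.data.frame(direct_estimates)) {
    de <- direct_estimates
  } else {
    de <- do.call(rbind, lapply(direct_estimates, function(e) {
      data.frame(treatment_a = e$treatment_a, treatment_b = e$treatment_b,
                 md = e$md, se = e$se, stringsAsFactors = FALSE)
    }))
  }
  m <- nrow(de)
  X <- matrix(0, m, length(d_names), dimnames = list(NULL, d_names))
  for (i in seq_len(m)) {
    a <- de$treatment_a[i]; b <- de$treatment_b[i]
    if (!all(c(a, b) %in% trts)) {
      stop("direct estimate names a treatment outside the network",
           call. = FALSE)
    }
    if (a %in% d_names) X[i, a] <- 1
    if (b %in% d_names) X[i, b] <- -1
  }
  w <- 1 / de$se^2
  XtWX <- crossprod(X, X * w)
  if (qr(XtWX)$rank < length(d_names)) {
    stop("singular design: network not identified by the direct estimates",
         call. = FALSE)
  }
  V <- solve(XtWX)
  beta <- drop(V %*% crossprod(X, w * de$md))
  d_full <- setNames(numeric(length(trts)), trts)
  d_full[d_names] <- beta
  Vfull <- matrix(0, length(trts), length(trts),
                  dimnames = list(trts, trts))
  Vfull[d_names, d_names] <- V
  z <- qnorm(0.975)
  out <- list()
  for (a in trts) for (b in trts) {
    if (a == b) next
    pt <- d_full[a] - d_full[b]
    se <- sqrt(Vfull[a, a] + Vfull[b, b] - 2 * Vfull[a, b])
    out[[length(out) + 1L]] <- data.frame(
      treatment_a = a, treatment_b = b, point = unname(pt), se = se,
      lower = unname(pt - z * se), upper = unname(pt + z * se),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
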