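#' Two-state gain/loss model
#'
#' A binary-trait continuous-time Markov model with independent gain
#' (`0 -> 1`, rate `q01`) and loss (`1 -> 0`, rate `q10`) rates per unit
#' branch length — the "all-rates-different" model for gene-family
#' presence/absence.
#'
#' @param q01 gain rate (>= 0).
#' @param q10 loss rate (>= 0).
#' @param root_prior distribution over states `{0, 1}` at the root; the
#'   default is uniform. `"stationary"` uses `(q10, q01)/(q01 + q10)`.
#' @return an object of class `two_state_model`.
#' @examples
#' m <- two_state_model(0.5, 1)
#' transition_probabilities(m, 0.5)
#' @export
two_state_model <- function(q01, q10, root_prior = c(0.5, 0.5)) {
  if (!is.finite(q01) || !is.finite(q10) || q01 < 0 || q10 < 0) {
    validation_error("rates must be finite and non-negative")
  }
  if (identical(root_prior, "stationary")) {
    if (q01 + q10 <= 0) validation_error("stationary prior undefined at zero rates")
    root_prior <- c(q10, q01) / (q01 + q10)
  }
  if (length(root_prior) != 2 || any(root_prior < 0) ||
      abs(sum(root_prior) - 1) > 1e-12) {
    validation_error("root prior must be a length-2 distribution")
  }
  structure(list(q01 = q01, q10 = q10, root_prior = as.numeric(root_prior)),
            class = "two_state_model")
}

#' Transition probability matrix of the two-state model
#'
#' Closed-form matrix exponential of `Q t` for
#' `Q = [[-q01, q01], [q10, -q10]]`:
#' `P00(t) = pi0 + pi1 exp(-(q01+q10) t)` with `pi0 = q10/(q01+q10)`, etc.
#'
#' @param model a [two_state_model()].
#' @param t branch length (>= 0).
#' @return a 2x2 row-stochastic matrix with dimnames `c("0", "1")`.
#' @export
transition_probabilities <- function(model, t) {
  if (!is.finite(t) || t < 0) validation_error("branch length must be >= 0")
  q01 <- model$q01; q10 <- model$q10
  q <- q01 + q10
  if (t == 0 || q == 0) {
    P <- diag(2)
  } else {
    pi1 <- q01 / q; pi0 <- q10 / q
    e <- exp(-q * t)
    P <- matrix(c(pi0 + pi1 * e, pi1 * (1 - e),
                  pi0 * (1 - e), pi1 + pi0 * e),
                nrow = 2, byrow = TRUE)
  }
  dimnames(P) <- list(c("0", "1"), c("0", "1"))
  P
}

#' Pruning (post-order) log-likelihood of tip presence/absence
#'
#' Felsenstein's pruning recursion for one binary family on a rooted tree:
#' the log of the root-prior-weighted sum over root states of the conditional
#' subtree likelihoods.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param tips named 0/1 vector covering every tip (names = tip labels), or
#'   an unnamed vector in `tree$tip.label` order.
#' @param model a [two_state_model()].
#' @return the log-likelihood (may be `-Inf` for structural zeros).
#' @export
pruning_loglik <- function(tree, tips, model) {
  ta <- tree_arrays(tree)
  st <- order_tip_states(tree, tips)
  cpp_pruning_loglik(ta$parent, ta$child, ta$elen, ta$ntip, ta$nnodes,
                     ta$root, st, model$q01, model$q10, model$root_prior)
}

#' Maximum-likelihood all-rates-different fit with a zero-rate floor
#'
#' Estimates `(q01, q10)` for one family by maximizing the pruning
#' log-likelihood in log-rate space (L-BFGS-B, three deterministic starts).
#' Any estimated rate that falls below `floor` — the near-zero exchange rates
#' that would otherwise leave a Q-matrix row at zero — is raised to exactly
#' `floor` after the fit and flagged; the reported log-likelihood is
#' re-evaluated at the returned (possibly floored) rates.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param tips named 0/1 tip-state vector.
#' @param floor minimum admissible rate (default `0.00001`).
#' @param root_prior root state prior (default uniform).
#' @param rate_bounds optimization box for the rates.
#' @return a `two_state_model` with extra fields `loglik`, `floored`
#'   (logical), `convergence`, and `floored_rates` (which of q01/q10 hit the
#'   floor).
#' @export
fit_ard <- function(tree, tips, floor = 0.00001, root_prior = c(0.5, 0.5),
                    rate_bounds = c(1e-8, 1e3)) {
  ta <- tree_arrays(tree)
  st <- order_tip_states(tree, tips)
  prior <- if (identical(root_prior, "stationary")) NULL else as.numeric(root_prior)
  nll <- function(logq) {
    p <- prior
    if (is.null(p)) {
      q <- exp(logq)
      p <- c(q[2], q[1]) / sum(q)
    }
    ll <- cpp_pruning_loglik(ta$parent, ta$child, ta$elen, ta$ntip, ta$nnodes,
                             ta$root, st, exp(logq[1]), exp(logq[2]), p)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  # crude initial rate: observed tip heterogeneity per unit tree length
  tot <- sum(ta$elen)
  p1 <- mean(st)
  base <- max(min(2 * p1 * (1 - p1) * length(st) / max(tot, 1e-8), 10), 1e-3)
  starts <- list(log(c(base, base)), log(c(base * 4, base / 4)),
                 log(c(base / 4, base * 4)))
  lb <- log(rate_bounds[1]); ub <- log(rate_bounds[2])
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      optim(pmin(pmax(s0, lb), ub), nll, method = "L-BFGS-B",
            lower = lb, upper = ub,
            control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    cladiv_error("ARD optimization failed from every start", "cladiv_optim_error")
  }
  q <- exp(best$par)
  floored <- q < floor
  q[floored] <- floor
  p <- prior %||% (c(q[2], q[1]) / sum(q))
  ll <- cpp_pruning_loglik(ta$parent, ta$child, ta$elen, ta$ntip, ta$nnodes,
                           ta$root, st, q[1], q[2], p)
  model <- two_state_model(q[1], q[2], p)
  model$loglik <- ll
  model$floored <- any(floored)
  model$floored_rates <- c(q01 = floored[1], q10 = floored[2])
  model$convergence <- best$convergence
  model
}

#' Fit the ARD model to every family of a presence/absence matrix
#'
#' @param tree rooted `phylo`.
#' @param mat 0/1 matrix (families x taxa; column names = tip labels).
#' @inheritParams fit_ard
#' @return a list with `models` (named list of fitted models) and `table`
#'   (data.frame `family_id`, `q01`, `q10`, `loglik`, `floored`).
#' @export
fit_ard_many <- function(tree, mat, floor = 0.00001, root_prior = c(0.5, 0.5)) {
  if (!setequal(colnames(mat), tree$tip.label)) {
    validation_error("matrix taxa must match tree tip labels")
  }
  fams <- rownames(mat)
  models <- vector("list", length(fams))
  names(models) <- fams
  for (f in fams) {
    tips <- setNames(mat[f, tree$tip.label], tree$tip.label)
    models[[f]] <- fit_ard(tree, tips, floor = floor, root_prior = root_prior)
  }
  table <- data.frame(
    family_id = fams,
    q01 = vapply(models, function(m) m$q01, numeric(1)),
    q10 = vapply(models, function(m) m$q10, numeric(1)),
    loglik = vapply(models, function(m) m$loglik, numeric(1)),
    floored = vapply(models, function(m) m$floored, logical(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(models = models, table = table)
}
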