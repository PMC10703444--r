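# Independent oracles: exhaustive enumeration over internal node states for
# the two-state CTMC likelihood and conditional marginals, a series-expansion
# matrix exponential, and a permutation-enumeration rank-sum p-value.

# log-likelihood and node marginals by brute-force summation over all 2^nint
# internal state assignments (trees up to ~8 tips)
enum_twostate <- function(tree, tips, model) {
  ta <- cladiv:::tree_arrays(tree)
  nint <- ta$nnodes - ta$ntip
  st <- numeric(ta$nnodes)
  st[seq_len(ta$ntip)] <- tips[ta$tip_label]
  Pe <- lapply(ta$elen, function(t) transition_probabilities(model, t))
  tot <- 0
  marg <- numeric(ta$nnodes)
  for (k in 0:(2^nint - 1)) {
    st[(ta$ntip + 1):ta$nnodes] <- as.integer(intToBits(k))[seq_len(nint)]
    p <- model$root_prior[st[ta$root] + 1]
    for (e in seq_along(ta$elen)) {
      p <- p * Pe[[e]][st[ta$parent[e]] + 1, st[ta$child[e]] + 1]
    }
    tot <- tot + p
    marg <- marg + p * st
  }
  list(loglik = log(tot), marginal = marg / tot)
}

# matrix exponential of Q*t by scaled Taylor series (no closed form)
series_pmat <- function(q01, q10, t, terms = 60) {
  Q <- matrix(c(-q01, q01, q10, -q10), 2, 2, byrow = TRUE)
  k <- max(1L, ceiling(t * max(q01, q10)))
  A <- Q * (t / k)
  P <- diag(2)
  term <- diag(2)
  for (i in seq_len(terms)) {
    term <- term %*% A / i
    P <- P + term
  }
  out <- diag(2)
  for (i in seq_len(k)) out <- out %*% P
  out
}

# exact one-tailed (greater) rank-sum p by enumerating all C(n1+n2, n1)
# assignments of the pooled ranks
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(ws >= w_obs)
}

# small random binary-state vector named by tree tips
random_tips <- function(tree) {
  setNames(sample(0:1, length(tree$tip.label), replace = TRUE), tree$tip.label)
}

# structural validity of a mapped history: events ordered and alternating
# within each branch, endpoints consistent, parity forced by endpoint states
check_history_consistency <- function(h) {
  for (e in seq_len(nrow(h$edge))) {
    a <- unname(h$node_state[h$edge[e, 1]])
    b <- unname(h$node_state[h$edge[e, 2]])
    ev <- h$events[h$events$edge == e, , drop = FALSE]
    if (nrow(ev) > 0) {
      testthat::expect_true(all(diff(ev$offset) > 0))
      testthat::expect_true(all(ev$offset > 0 &
                                  ev$offset < h$edge_length[e] + 1e-12))
      states <- c(a, ev$to_state)
      testthat::expect_true(all(abs(diff(states)) == 1))
      testthat::expect_identical(states[length(states)], as.integer(b))
    } else {
      testthat::expect_identical(as.integer(a), as.integer(b))
    }
    testthat::expect_identical(nrow(ev) %% 2L, as.integer(abs(a - b)) %% 2L)
  }
}

random_tree <- function(ntip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(ntip)
  tr$tip.label <- sprintf("t%02d", seq_len(ntip))
  attr(tr, "units") <- "subst/site"
  tr
}
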