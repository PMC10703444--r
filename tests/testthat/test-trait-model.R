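test_that("transition kernel matches the closed form and its limits", {
  m <- two_state_model(2, 1)
  expect_equal(transition_probabilities(m, 0), diag(2), ignore_attr = TRUE)
  # symmetric stationary limit
  ms <- two_state_model(1, 1)
  expect_equal(unname(transition_probabilities(ms, 500)),
               matrix(0.5, 2, 2), tolerance = 1e-12)
  # P00(0.5) = 1/3 + (2/3) e^{-1.5}
  expect_equal(transition_probabilities(m, 0.5)[1, 1],
               1 / 3 + (2 / 3) * exp(-1.5), tolerance = 1e-12)
  expect_error(transition_probabilities(m, -1), ">= 0")
})

test_that("transition kernel agrees with a series matrix exponential", {
  set.seed(14)
  for (i in 1:20) {
    q01 <- runif(1, 0.01, 4); q10 <- runif(1, 0.01, 4); t <- runif(1, 0, 5)
    P <- transition_probabilities(two_state_model(q01, q10), t)
    expect_equal(unname(P), series_pmat(q01, q10, t), tolerance = 1e-9)
    expect_equal(rowSums(P), c("0" = 1, "1" = 1), tolerance = 1e-12)
  }
})

test_that("Chapman-Kolmogorov holds for random models", {
  set.seed(21)
  for (i in 1:25) {
    m <- two_state_model(runif(1, 0.01, 5), runif(1, 0.01, 5))
    t1 <- runif(1, 0, 5); t2 <- runif(1, 0, 5)
    expect_equal(transition_probabilities(m, t1 + t2),
                 transition_probabilities(m, t1) %*% transition_probabilities(m, t2),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("pruning likelihood equals exhaustive enumeration", {
  # single tip: log prior mass of the observed state
  tip <- read_newick("(A:1);", default_length = 1)
  m <- two_state_model(1, 1, "stationary")
  expect_equal(pruning_loglik(tip, c(A = 1), m), log(0.5))

  # two tips: explicit two-term sum over the root state
  tr2 <- read_newick("(A:0.7,B:1.3);")
  m2 <- two_state_model(0.4, 0.9)
  byhand <- log(sum(vapply(0:1, function(s) {
    m2$root_prior[s + 1] *
      transition_probabilities(m2, 0.7)[s + 1, 2] *
      transition_probabilities(m2, 1.3)[s + 1, 2]
  }, numeric(1))))
  expect_equal(pruning_loglik(tr2, c(A = 1, B = 1), m2), byhand, tolerance = 1e-12)

  # random trees up to 6 tips vs enumeration
  set.seed(77)
  for (i in 1:15) {
    tr <- random_tree(sample(3:6, 1))
    m3 <- two_state_model(exp(runif(1, -2, 1)), exp(runif(1, -2, 1)))
    tips <- random_tips(tr)
    expect_equal(pruning_loglik(tr, tips, m3),
                 enum_twostate(tr, tips, m3)$loglik, tolerance = 1e-9)
  }
})

test_that("pruning likelihood is invariant to child order", {
  set.seed(3)
  tr <- random_tree(7)
  tips <- random_tips(tr)
  m <- two_state_model(0.7, 0.3)
  base <- pruning_loglik(tr, tips, m)
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  expect_equal(pruning_loglik(rot, tips[rot$tip.label], m), base, tolerance = 1e-12)
})

test_that("pruning likelihood agrees with an independent Mk fit engine", {
  skip_if_not_installed("phytools")
  set.seed(8)
  tr <- random_tree(10)
  tips <- random_tips(tr)
  m <- two_state_model(0.6, 1.1)
  fitmk <- phytools::fitMk(tr, setNames(as.character(tips), names(tips)),
                           model = "ARD", fixedQ = matrix(c(-0.6, 0.6, 1.1, -1.1),
                                                          2, 2, byrow = TRUE,
                                                          dimnames = list(0:1, 0:1)),
                           pi = c(0.5, 0.5))
  expect_equal(pruning_loglik(tr, tips, m), fitmk$logLik, tolerance = 1e-6)
})

test_that("ARD fit recovers rates and applies the zero-rate floor", {
  set.seed(61)
  tr <- random_tree(64)
  true <- two_state_model(0.5, 1.0)
  ta <- cladiv:::tree_arrays(tr)
  est <- t(replicate(60, {
    st <- cladiv:::sim_states_forced(ta, 0.5, 1.0)
    tips <- setNames(st[seq_len(ta$ntip)], ta$tip_label)
    f <- fit_ard(tr, tips)
    c(f$q01, f$q10)
  }))
  expect_lt(abs(median(est[, 1]) / 0.5 - 1), 0.25)
  expect_lt(abs(median(est[, 2]) / 1.0 - 1), 0.25)

  # all-present family: loss rate floored at exactly 0.00001 and flagged
  f <- fit_ard(tr, setNames(rep(1, 64), tr$tip.label))
  expect_identical(f$q10, 0.00001)
  expect_true(f$floored)
  expect_true(f$floored_rates["q10"])
})

test_that("ARD optimum dominates random rate pairs", {
  set.seed(55)
  tr <- random_tree(16)
  tips <- random_tips(tr)
  fit <- fit_ard(tr, tips)
  lls <- replicate(100, {
    m <- two_state_model(exp(runif(1, log(1e-4), log(50))),
                         exp(runif(1, log(1e-4), log(50))),
                         fit$root_prior)
    pruning_loglik(tr, tips, m)
  })
  expect_true(all(fit$loglik >= lls - 1e-6))
})

test_that("equal-rates data yield no spurious rate asymmetry", {
  set.seed(88)
  tr <- random_tree(48)
  ta <- cladiv:::tree_arrays(tr)
  ratio <- replicate(40, {
    st <- cladiv:::sim_states_forced(ta, 0.8, 0.8)
    tips <- setNames(st[seq_len(ta$ntip)], ta$tip_label)
    f <- fit_ard(tr, tips)
    log(f$q01 / f$q10)
  })
  expect_lt(abs(median(ratio)), 0.35)
})
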