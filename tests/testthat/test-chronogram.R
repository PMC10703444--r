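# a small noiseless strict-clock dating fixture with exactly recoverable ages
clock_fixture <- function(seed = 3, n_tips = 16, depth_my = 100) {
  spec <- synthetic_spec(seed = seed, n_tips = n_tips, depth_my = depth_my,
                         subst_rate = 1e-4, sites = 10000, noiseless = TRUE)
  tr <- simulate_tree(spec, dating = TRUE)
  list(tree = tr, ages = attr(tr, "true_ages"), sites = spec$sites,
       root = length(tr$tip.label) + 1L)
}

test_that("PL objective: zero-penalty optimum, monotone penalty, dominance", {
  fx <- clock_fixture(n_tips = 8)
  tr <- fx$tree
  nn <- length(fx$ages)
  rates <- rep(1e-4, nrow(tr$edge))
  base <- pl_objective(tr, fx$ages, rates, lambda = 5, sites = fx$sites)
  expect_true(is.finite(base))

  # equal rates: penalty is zero, so lambda does not change the objective
  expect_equal(pl_objective(tr, fx$ages, rates, 50, fx$sites), base)

  # with rate heterogeneity, doubling lambda can only lower the objective
  set.seed(4)
  r2 <- rates * exp(rnorm(length(rates), 0, 0.3))
  o1 <- pl_objective(tr, fx$ages, r2, 5, fx$sites)
  o2 <- pl_objective(tr, fx$ages, r2, 10, fx$sites)
  expect_lt(o2, o1)

  # infeasible ages yield the -Inf marker, not an error
  bad <- fx$ages
  bad[fx$root] <- 0
  expect_identical(pl_objective(tr, bad, rates, 5, fx$sites), -Inf)

  # true parameters dominate random feasible perturbations
  set.seed(11)
  for (i in 1:50) {
    ages_p <- fx$ages * runif(1, 0.5, 1.5)
    ages_p[seq_len(8)] <- 0
    jit <- fx$ages + c(rep(0, 8), runif(nn - 8, -1, 1))
    jit[fx$root] <- fx$ages[fx$root]
    use <- if (i %% 2 == 0) ages_p else jit
    r_p <- rates * exp(rnorm(length(rates), 0, 0.2))
    alt <- pl_objective(tr, use, r_p, 5, fx$sites)
    expect_lte(alt, base + 1e-9)
  }
})

test_that("noiseless clock ages are recovered for a range of smoothing values", {
  fx <- clock_fixture()
  cal <- calibration_set(list(fx$tree$tip.label),
                         fx$ages[fx$root], fx$ages[fx$root], "root")
  internal <- (length(fx$tree$tip.label) + 1L):length(fx$ages)
  for (lam in c(1, 100)) {
    fit <- fit_chronogram(fx$tree, cal, lambda = lam, sites = fx$sites)
    rel <- abs(fit$ages[internal] - fx$ages[internal]) / fx$ages[internal]
    expect_lt(max(rel), 1e-4)
    expect_true(all(fit$compliance$ok))
  }
})

test_that("calibration bounds are honored and infeasible sets rejected", {
  spec <- synthetic_spec(seed = 9, n_tips = 12, depth_my = 4000,
                         subst_rate = 5e-5, sites = 10000)
  tr <- simulate_tree(spec, dating = TRUE)
  cal <- fixture_calibrations(tr)     # root [3460, 4400] plus event anchors
  fit <- fit_chronogram(tr, cal, lambda = 10, sites = 10000)
  expect_true(all(fit$compliance$ok))
  expect_gte(unname(fit$ages[13]), 3460)
  expect_lte(unname(fit$ages[13]), 4400)
  ord <- fit$ages[tr$edge[, 1]] - fit$ages[tr$edge[, 2]]
  expect_true(all(ord >= 0))

  # descendant min above ancestor max is rejected with a named validation error
  bad <- calibration_set(list(tr$tip.label, attr(tr, "focal_tips")),
                         c(NA, 5000), c(4400, NA), c("root", "deep_min"))
  expect_error(fit_chronogram(tr, bad, 10, 10000), "infeasible")
})

test_that("the heavy-smoothing limit matches a strict-clock fit", {
  fx <- clock_fixture()
  cal <- calibration_set(list(fx$tree$tip.label),
                         fx$ages[fx$root], fx$ages[fx$root], "root")
  internal <- (length(fx$tree$tip.label) + 1L):length(fx$ages)
  f_inf <- fit_chronogram(fx$tree, cal, lambda = 1e8, sites = fx$sites)
  f_clk <- fit_chronogram(fx$tree, cal, lambda = 0, sites = fx$sites, clock = TRUE)
  rel <- abs(f_inf$ages[internal] - f_clk$ages[internal]) / f_clk$ages[internal]
  expect_lt(max(rel), 1e-3)
  expect_lt(var(f_inf$rates), 1e-12 * mean(f_inf$rates)^2)
})

test_that("rescaling calibrations rescales ages and inverts rates", {
  fx <- clock_fixture(n_tips = 8)
  cal1 <- calibration_set(list(fx$tree$tip.label),
                          fx$ages[fx$root], fx$ages[fx$root], "root")
  cc <- 10
  cal2 <- calibration_set(list(fx$tree$tip.label),
                          cc * fx$ages[fx$root], cc * fx$ages[fx$root], "root")
  # lambda scales with c^2: the additive penalty carries units of rate^2
  f1 <- fit_chronogram(fx$tree, cal1, lambda = 2, sites = fx$sites)
  f2 <- fit_chronogram(fx$tree, cal2, lambda = 2 * cc^2, sites = fx$sites)
  internal <- (length(fx$tree$tip.label) + 1L):length(fx$ages)
  expect_equal(unname(f2$ages[internal]), unname(cc * f1$ages[internal]),
               tolerance = 1e-6)
  expect_equal(f2$rates, f1$rates / cc, tolerance = 1e-6)
})

test_that("a relaxed-clock clade is dated better by PL than by a strict clock", {
  # one clade 5x faster than the background rate
  spec <- synthetic_spec(seed = 21, n_tips = 16, depth_my = 100,
                         subst_rate = 1e-4, sites = 50000)
  tr <- simulate_tree(spec, dating = TRUE)
  truth <- attr(tr, "true_ages")
  cr <- find_crown_node(tr, focal_clade(tr))
  fast <- c(cr$node, unlist(phangorn::Descendants(tr, cr$node, "all")))
  sel <- tr$edge[, 2] %in% fast
  tr$edge.length[sel] <- tr$edge.length[sel] * 5
  cal <- calibration_set(list(tr$tip.label), truth[17], truth[17], "root")
  f_pl <- fit_chronogram(tr, cal, lambda = 0.1, sites = spec$sites)
  f_ck <- fit_chronogram(tr, cal, lambda = 0, sites = spec$sites, clock = TRUE)
  rmse <- function(a) sqrt(mean((a[18:31] - truth[18:31])^2))
  expect_lt(rmse(f_pl$ages), rmse(f_ck$ages))
})

test_that("cross-validation selects smoothing deterministically", {
  fx <- clock_fixture(n_tips = 8)
  cal <- calibration_set(list(fx$tree$tip.label),
                         fx$ages[fx$root], fx$ages[fx$root], "root")
  # grid of one value: that value is chosen
  cv1 <- cross_validate(fx$tree, cal, 7, scheme = "cv", sites = fx$sites)
  expect_equal(attr(cv1, "chosen"), 7)

  # clock-like data: heavy smoothing never predicts worse than none
  cv2 <- cross_validate(fx$tree, cal, c(0.01, 1000), scheme = "randomcv",
                        sites = fx$sites, seed = 5, n_random = 2)
  expect_lte(cv2$error[cv2$lambda == 1000], cv2$error[cv2$lambda == 0.01] + 1e-9)

  # same seed, same report
  cv3 <- cross_validate(fx$tree, cal, c(0.01, 1000), scheme = "randomcv",
                        sites = fx$sites, seed = 5, n_random = 2)
  expect_identical(cv2, cv3)

  small <- ape::rtree(3); small$tip.label <- c("a", "b", "c")
  expect_error(cross_validate(small, cal, 1, sites = 100), "4 tips")
})
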