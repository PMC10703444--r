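test_that("tree simulation is deterministic, ultrametric, and clock-consistent", {
  spec <- synthetic_spec(seed = 1, n_tips = 16)
  t1 <- simulate_tree(spec)
  t2 <- simulate_tree(spec)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(ape::is.ultrametric(t1, tol = 1e-8))
  expect_equal(max(ape::node.depth.edgelength(t1)), spec$depth, tolerance = 1e-9)

  # lognormal with sigma 0 equals the strict clock
  s_strict <- synthetic_spec(seed = 2, n_tips = 12, clock = "strict")
  s_ln0 <- synthetic_spec(seed = 2, n_tips = 12, clock = "lognormal",
                          clock_sigma = 0)
  expect_identical(write_newick(simulate_tree(s_strict, dating = TRUE)),
                   write_newick(simulate_tree(s_ln0, dating = TRUE)))

  # dating fixture exposes true ages consistent with its branch lengths
  d <- simulate_tree(s_strict, dating = TRUE)
  ages <- attr(d, "true_ages")
  dur <- ages[d$edge[, 1]] - ages[d$edge[, 2]]
  expect_equal(d$edge.length, dur * attr(d, "true_rates"), tolerance = 1e-9)
  expect_equal(unname(ages[13]), s_strict$depth_my, tolerance = 1e-6)
})

test_that("family simulation plants the signal it reports", {
  spec <- synthetic_spec(seed = 5, n_tips = 32, n_families = 60, n_planted = 15,
                         planted_gain_prob = 1)
  tr <- simulate_tree(spec)
  fam <- simulate_families(spec, tr)
  # gain probability 1: every planted family truly gained at the crown
  expect_true(all(fam$truth$stem_gain[fam$truth$planted]))
  expect_false(any(fam$truth$planted[-(1:15)]))
  # no all-absent row survives
  expect_true(all(rowSums(fam$matrix) > 0))
  # the true-gain oracle agrees with gain counting on the true node states
  ta <- cladiv:::tree_arrays(tr)
  stem_parent <- ta$parent[ta$child == fam$crown$node]
  recount <- fam$node_states[, stem_parent] == 0L &
    fam$node_states[, fam$crown$node] == 1L
  expect_equal(unname(recount), fam$truth$stem_gain)
  # matrix equals the tip slice of the true states
  expect_equal(unname(fam$matrix), unname(fam$node_states[, seq_len(ta$ntip)]))
})

test_that("planted stem-gain frequency tracks the requested probability", {
  spec <- synthetic_spec(seed = 8, n_tips = 32, n_families = 200,
                         n_planted = 200, planted_gain_prob = 0.8)
  tr <- simulate_tree(spec)
  fam <- simulate_families(spec, tr)
  rate <- mean(fam$truth$stem_gain)
  expect_lt(abs(rate - 0.8), 3 * sqrt(0.8 * 0.2 / 200) + 0.02)
})

test_that("annotation emulation supports majority-rule recovery", {
  spec0 <- synthetic_spec(seed = 3, n_tips = 16, n_families = 40,
                          n_planted = 5, annotation_noise = 0)
  tr <- simulate_tree(spec0)
  fam <- simulate_families(spec0, tr)
  ann <- emulate_annotation_table(spec0, fam$matrix)
  mr <- majority_rule_ko(ann$membership, best_scored_annotation(ann$annotations))
  got <- setNames(mr$assignments$ko_id, mr$assignments$family_id)
  truth <- setNames(ann$true_ko$ko_id, ann$true_ko$family_id)
  # zero noise: every family's KO recovered exactly
  expect_identical(got[names(truth)], truth)

  # 20% noise with enough members: recovery at >= 95%
  spec2 <- synthetic_spec(seed = 4, n_tips = 32, n_families = 150,
                          n_planted = 10, annotation_noise = 0.2)
  tr2 <- simulate_tree(spec2)
  fam2 <- simulate_families(spec2, tr2)
  keep <- rowSums(fam2$matrix) >= 5
  ann2 <- emulate_annotation_table(spec2, fam2$matrix)
  mr2 <- majority_rule_ko(ann2$membership, best_scored_annotation(ann2$annotations))
  got2 <- setNames(mr2$assignments$ko_id, mr2$assignments$family_id)
  truth2 <- setNames(ann2$true_ko$ko_id, ann2$true_ko$family_id)
  fams5 <- ann2$true_ko$family_id[keep]
  expect_gte(mean(got2[fams5] == truth2[fams5]), 0.95)

  # full noise: recovery collapses to chance
  spec3 <- synthetic_spec(seed = 6, n_tips = 16, n_families = 60,
                          n_planted = 5, annotation_noise = 1)
  tr3 <- simulate_tree(spec3)
  fam3 <- simulate_families(spec3, tr3)
  ann3 <- emulate_annotation_table(spec3, fam3$matrix)
  mr3 <- majority_rule_ko(ann3$membership, best_scored_annotation(ann3$annotations))
  got3 <- setNames(mr3$assignments$ko_id, mr3$assignments$family_id)
  truth3 <- setNames(ann3$true_ko$ko_id, ann3$true_ko$family_id)
  expect_lt(mean(got3[names(truth3)] == truth3, na.rm = TRUE), 0.3)
})

test_that("bundle writing emits the dialects the pipeline consumes", {
  spec <- synthetic_spec(seed = 2, n_tips = 12, n_families = 25, n_planted = 5)
  b <- generate_bundle(spec, dating = TRUE)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_true(all(file.exists(file.path(dir,
    c("tree.nwk", "matrix.tsv", "membership.tsv", "annotations.tsv",
      "ko_category.tsv", "family_ko.tsv", "clade.txt", "dating_tree.nwk",
      "calibrations.tsv", "manifest.json")))))
  tr <- read_newick(file.path(dir, "tree.nwk"))
  mat <- read_trait_matrix(file.path(dir, "matrix.tsv"))
  expect_setequal(colnames(mat), tr$tip.label)
  cal <- read_calibrations(file.path(dir, "calibrations.tsv"))
  expect_true("root" %in% cal$label)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$spec$seed, 2)

  # byte-identical regeneration under the same seed
  dir2 <- withr::local_tempdir()
  write_bundle(generate_bundle(synthetic_spec(seed = 2, n_tips = 12,
                                              n_families = 25, n_planted = 5),
                               dating = TRUE), dir2)
  for (f in c("tree.nwk", "matrix.tsv", "annotations.tsv", "manifest.json")) {
    expect_identical(readLines(file.path(dir, f)), readLines(file.path(dir2, f)))
  }
})
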