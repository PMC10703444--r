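# cladiv

Comparative-genomic machinery for characterising and dating the
diversification of microbial clades on a rooted phylogeny. Given a tree, a
gene-family presence/absence matrix, and functional annotations, `cladiv`
answers two questions about a focal clade:

1. **What did the clade gain when it diversified?** Each family evolves as a
   two-state (gain/loss) continuous-time Markov chain with independent rates
   `q01` (0→1) and `q10` (1→0), fitted per family by maximum likelihood
   ("all-rates-different" model) with near-zero rates floored at exactly
   `0.00001`. Stochastic mapping samples full gain/loss histories
   conditional on the tip data (backward–forward sampling plus exact
   endpoint-conditioned path sampling by uniformization); a constant-rate
   null simulates the same fitted process forward *without* conditioning on
   the tips. Per functional category (KEGG KOs resolved by best-score
   filtering and majority rule), the number of families gained on the
   clade's stem branch is counted in each of N = 100 replicates per sampler,
   and the mapped and null count distributions are compared with a
   one-tailed Wilcoxon rank-sum test (α = 0.01): categories with
   significantly more mapped gains are *enriched* at the crown node.

2. **When did it diversify?** Penalized-likelihood dating converts the
   substitutions/site tree into node ages (My): branch substitution counts
   `x_i = round(b_i · sites)` are Poisson with mean `r_i t_i · sites`, rate
   heterogeneity is penalized by `λ · Φ` (squared differences between each
   branch's rate and its parent's, TreePL-style), and min/max node-age
   calibrations — geological anchors such as a 3460–4400 My root window or a
   2320 My oxygenation bound — are enforced by construction. The smoothing
   value λ is chosen by cross-validation on held-out terminal branches
   (`cv` / `randomcv` schemes).

Supporting metrics include internode certainty / tree certainty (entropy of
each reference bipartition against its most prevalent conflicting
bipartition across replicate trees) for tree-quality assessment, and a
synthetic-data generator that plants a known crown-node gain signal in one
category so the whole pipeline can be validated end to end without any
external data.

Intended users: microbial comparative genomicists and molecular evolution
researchers studying when clades diversified and which functions they
acquired — and anyone needing a tested, scriptable reimplementation of this
analysis style.

## Worked example

Generate a synthetic bundle with a planted signal (32 taxa, 120 families of
which 20 planted in category `planted` with stem-gain probability 0.8), run
the full analysis, and test for enrichment:

```r
library(cladiv)

spec   <- synthetic_spec(seed = 42, n_tips = 32, n_families = 120,
                         n_planted = 20, n_categories = 6)
bundle <- generate_bundle(spec)

# annotation: best-scored hit per protein, then majority rule per family
anns    <- best_scored_annotation(bundle$annotations)
kos     <- majority_rule_ko(bundle$membership, anns)
fam_cat <- category_map(kos$assignments, bundle$ko_category)

# per-family ARD fits, then 100 mapped + 100 null histories per family
fits  <- fit_ard_many(bundle$tree, bundle$matrix)
gains <- run_replicates(bundle$tree, bundle$matrix, fits$models,
                        bundle$crown, n = 100, seed = 42)

counts     <- aggregate_category_counts(gains, fam_cat)
enrichment <- call_enrichment(counts, alpha = 0.01)
enrichment[, c("category_id", "n_families", "p_value", "enriched",
               "mapped_median", "null_median")]
```

```
  category_id n_families  p_value enriched mapped_median null_median
1     planted         20 1.12e-31     TRUE             2           0
2        BG05         20 1.70e-01    FALSE             0           0
3        BG03         20 6.57e-01    FALSE             0           0
4        BG02         20 7.96e-01    FALSE             0           0
5        BG04         20 8.86e-01    FALSE             0           0
6        BG01         20 9.82e-01    FALSE             0           0
```

The planted category is recovered decisively: across the 100 stochastic-
mapping replicates the median number of its families gained on the focal
stem branch is 2, versus 0 under the constant-rate null, giving a one-tailed
rank-sum p of ~1e-31 — far below α = 0.01. The five background categories
stay non-significant. (Median 2 of 20 planted families per replicate is
expected: a mapped gain requires the sampled history to place the gain on
the stem branch itself, and fitted-rate histories distribute some gains onto
neighbouring branches.)

Dating works from a calibration set; here the root is constrained to a
geological-style window and compliance is reported per calibration:

```r
dspec <- synthetic_spec(seed = 42, n_tips = 16, depth_my = 4000,
                        subst_rate = 5e-5, sites = 10000)
dtree <- simulate_tree(dspec, dating = TRUE)
cal   <- fixture_calibrations(dtree, root_bounds = c(3460, 4400),
                              event_age = 2320)
cv    <- cross_validate(dtree, cal, lambda_grid = c(1, 10, 100),
                        scheme = "randomcv", sites = 10000, seed = 42)
chrono <- fit_chronogram(dtree, cal, lambda = attr(cv, "chosen"),
                         sites = 10000)
chrono$compliance
```

Every returned chronogram satisfies all calibrations and parent > child
ordering by construction. `run_pipeline(pipeline_config(...))` chains all
stages (content → fit → sample → test, plus optional dating and
tree-certainty stages) behind one configuration with per-stage TSV outputs,
a JSON summary, and resumable intermediates.

See the vignette (`vignettes/crown-gains.Rmd`) for the models, parameter
choices, numerical details, and limitations.

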