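---
title: "Dating clade diversification and testing crown-node gene gains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating clade diversification and testing crown-node gene gains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`cladiv` asks two questions about a clade on a rooted phylogeny: *when* did
it diversify, and *what gene functions did it gain* when it did. This
vignette describes the models behind each answer, the tunable parameters and
their defaults, what the synthetic-data generator does and does not emulate,
and the numerical choices and known limitations a user should be aware of.

## The gain/loss model

Each gene family is a binary character (present/absent) evolving along the
tree under a two-state continuous-time Markov chain with gain rate $q_{01}$
and loss rate $q_{10}$ per unit branch length — the "all-rates-different"
(ARD) model. The transition kernel has the closed form

$$P_{00}(t) = \pi_0 + \pi_1 e^{-(q_{01}+q_{10})t}, \qquad
  \pi_0 = \frac{q_{10}}{q_{01}+q_{10}},$$

and likelihoods are computed by Felsenstein's pruning recursion with
per-node rescaling (`pruning_loglik()`, implemented in C++). Rates are
estimated per family by maximum likelihood in log-rate space (L-BFGS-B,
three deterministic starts within bounds $[10^{-8}, 10^3]$). Families that
are present (or absent) in every tip drive one rate toward zero, leaving a
Q-matrix row at zero; following standard practice for this analysis, any
estimated rate below the **rate floor** (default `0.00001`) is raised to
exactly the floor after the fit and flagged (`fit_ard()`). The floor is a
post-fit repair, not an optimization bound, so the reported likelihood is
re-evaluated at the floored rates.

The **root prior** defaults to uniform $(0.5, 0.5)$, the convention of the
stochastic-mapping tools this package mirrors; a stationary or fixed prior
is available. This choice matters mostly for families with little signal:
a stationary prior at strongly asymmetric fitted rates would pull ancestral
states toward the majority state.

## Stochastic mapping and the constant-rate null

`sample_conditional_history()` draws complete gain/loss histories
conditional on the observed tips: a backward pass computes conditional
subtree likelihoods, node states are then sampled root-to-tips from their
joint conditional distribution, and each branch path is filled in by
**uniformization** — an endpoint-conditioned path sampler with dominating
rate $\mu = \max(q_{01}, q_{10})(1+\varepsilon)$ that is exact and always
terminates, unlike naive rejection sampling on short branches whose
endpoints differ. Sampled histories reproduce the tip data exactly (this is
asserted on every draw).

`sample_unconditional_history()` is the null: the same fitted rates, but the
process is simulated forward from the root prior by exponential waiting
times, ignoring the tips. The contrast between the two distributions of
**crown-node gains** is the quantity of interest.

A *gain at the crown node* defaults to the net state change across the stem
branch (parent node absent, crown node present). The phrase "gained at the
crown node" is ambiguous between this and counting $0 \to 1$ events on the
stem branch, so an event-count mode is provided (`gain_indicator(mode =
"events")`); the net-gain semantics drive the headline test because a gain
that is immediately lost again on the stem branch has not been acquired by
the crown group. Whether gains should instead be summed over the crown
node's child branches is a further open reading; the stem-branch semantics
are implemented and the alternative is reachable by calling
`gain_indicator()` on any node.

With `run_replicates()` (default **N = 100** replicates per sampler,
matching the analysis constants this package reproduces), per-family RNG
substreams are derived from `(seed, family id, sampler kind)`, so results do
not depend on the order families are processed. Replicates within a family
are drawn sequentially inside that substream.

## Enrichment testing

Families are annotated by their KEGG ortholog (KO): per-protein hits are
filtered to the best score (`best_scored_annotation()`, ties to the
lexicographically smaller KO), and each cluster takes the majority KO of its
members (`majority_rule_ko()`, frequency ties to the higher mean score, then
lexicographic). Majority rule operates on KO identifiers, not on category
labels, the more conservative of the two readings. Unannotated clusters are
discarded and reported.

Per category and replicate, gains are summed over the category's families;
mapped and null count vectors are compared with a **one-tailed two-sample
rank-sum (Mann–Whitney) test** of "mapped stochastically greater"
(`rank_sum_one_tailed()`), exact by enumeration when both samples have at
most 10 values without ties, otherwise the normal approximation with tie and
continuity corrections. The two replicate sets are independent draws, which
is why the two-sample form is used rather than a paired signed-rank test.
A category is **enriched** when $p < \alpha$ (default $\alpha = 0.01$) in
the mapped-greater direction; no multiple-testing correction is applied by
default (Benjamini–Hochberg is available via `adjust = "BH"`). Categories
with identical constant counts in both samplers are reported as degenerate
non-enriched rather than dropped.

**A limitation worth understanding:** with $N = 100$ replicates per side,
the rank-sum test detects *any* consistent shift, however small. A single
family that truly gained at the focal node — even by chance, with no
category-level signal — produces mapped gains near 1 in every replicate
while the unconditional null stays at the family's marginal gain rate, and
the category containing it will be called enriched with a vanishingly small
p-value. Category enrichment calls therefore respond to individual chance
gains, not only to systematic category-level elevation; at realistic gene
gain rates some "background" categories will be flagged in any given run.
Interpreting enrichment lists should account for this sensitivity.

## Penalized-likelihood dating

`fit_chronogram()` converts a substitutions/site tree into node ages (My)
and per-branch rates by maximizing a penalized likelihood: each branch's
implied substitution count $x_i = \mathrm{round}(b_i \cdot \text{sites})$ is
Poisson with mean $r_i t_i \cdot \text{sites}$, and rate heterogeneity is
penalized by $\lambda \Phi$ with $\Phi$ the sum of squared differences
between each branch's rate and its parent branch's (count scale) plus the
variance of the root's child rates — the additive, natural-scale penalty of
the standard PL dating tools. `sites` is a required input because the
Poisson formulation needs counts; no default is asserted. Because the
penalty has units of (count rate)$^2$, $\lambda$ is not dimensionless:
rescaling all ages by $c$ maps an optimum to an optimum only when $\lambda$
is rescaled by $c^2$, which is how the package's scale-consistency test is
phrased.

Feasibility is built into the parameterization rather than enforced by
penalties: internal-node ages are placed in pre-order as proportions between
each node's effective floor (the maximum of its own and its descendants'
minimum calibrations) and ceiling (the smaller of its parent's age and its
ancestors' maxima). Every iterate — and hence every returned chronogram —
satisfies parent > child ordering and all min/max calibrations; infeasible
calibration sets (a descendant minimum above an ancestor maximum) are
rejected up front with the offending node named. Candidate ages passed
directly to `pl_objective()` that violate ordering return `-Inf` as an
infeasibility marker rather than an error.

Numerical choices: optimization is joint L-BFGS-B over age proportions and
log rates with three deterministic starts (path-proportional initial ages; a
polishing restart tightens convergence); for heavily smoothed fits
($\lambda \ge 100$) the optimizer is seeded at the strict-clock solution
(`clock = TRUE` fit), whose neighbourhood contains the optimum — far from
it, the penalty-dominated surface is too ill-conditioned for reliable
progress. Zero-length branches are kept at zero. With only min/max *window*
calibrations the likelihood is exactly flat along a rescaling of all ages
(rates absorb the change), and the penalty weakly prefers older, slower
solutions — a real property of penalized-likelihood dating: at least one
fixed (or tightly bounded) calibration is needed to identify the absolute
time scale.

`cross_validate()` selects $\lambda$ by hiding terminal branches (each in
turn, or random subsets under `scheme = "randomcv"`), refitting without
their Poisson terms, and scoring $\sum_i (x_i - \hat{x}_i)^2 / \hat{x}_i$
with $\hat{x}_i$ predicted from the parent-side rate and the hidden branch's
fitted duration. `priors_set2()` drops maximum-only calibrations (the
oxygen-ceiling style constraints) for sensitivity analysis, and
`compare_prior_sets()` reports the per-node age deltas.

## Tree certainty

`internode_certainty()` scores every non-trivial bipartition of a reference
tree against a replicate set: with $p_1$ the bipartition's frequency and
$p_2$ the frequency of its most prevalent *conflicting* bipartition
(incompatibility judged on unrooted trees, so rooting differences are not
conflict), the internode certainty is
$1 + p_1'\log_2 p_1' + p_2'\log_2 p_2'$ on the renormalized pair, negated
when the conflict dominates. `tree_certainty()` is the mean over internal
branches (the *relative* TC, in $[-1, 1]$). This is the two-term variant —
only the single strongest conflict enters — which is the variant computable
from a reference tree plus replicates; published TC values computed over all
conflicting bipartitions are not numerically comparable and are not treated
as reproduction targets here.

## What the synthetic generator emulates

`synthetic_spec()` fixes the validation conditions: a pure-birth topology
(64 tips, unit depth), 300 families with per-family $(q_{01}, q_{10})$
log-uniform on $[0.01, 0.3]$, one focal clade (~25% of tips), 30 *planted*
families forced to state 0 at the crown's parent and state 1 at the crown
with probability 0.8, one protein per present taxon with 5% annotation
noise, and for dating fixtures a 4000 My depth at $5 \times 10^{-5}$
subst/site/My over 10000 sites with strict or lognormal branch rates.

The rate range deserves its justification: real gene families are gained
rarely — a family typically originates once on a tree and is then retained
or sporadically lost. Log-uniform rates on $[0.01, 0.3]$ put the expected
number of gains per family per tree at or below order one and the chance of
a background gain on any particular internal branch at the $10^{-3}$ to
$10^{-2}$ level. At substantially higher rates, "background" families gain
at the focal stem by chance so often that background categories carry real
signal and the planted/background contrast the generator is supposed to
embody disappears. Even in this regime, occasional chance background gains
occur and are flagged by the test (see the limitation above) — that is the
method behaving as designed, not a generator artifact.

Planting acts on the true history (the stem endpoints), not on tip
patterns, so the mapped-vs-null contrast measures the planted quantity
itself. The generator does **not** emulate: paralog-rich clusters (a
multiplier exists but defaults to off), horizontal transfer as a distinct
process (chance CTMC gains stand in for it), rate variation across branches
for the trait process, correlated families, incomplete genomes/annotation
dropout, or realistic KEGG hierarchy structure. Passing tests on these
fixtures therefore validate the *machinery* — likelihoods, samplers, test
calibration, optimizer correctness — not robustness to those real-data
complications.

Dating fixtures optionally snap true node ages to the grid on which
substitution counts are exact integers (`noiseless = TRUE`), making the
truth exactly recoverable; this isolates optimizer error from rounding
noise when validating age recovery.

## Problem sizes and determinism

The test suite exercises: exhaustive-enumeration likelihood checks on all
rooted topologies with 3–6 tips; conditional-marginal checks with 10,000
sampler draws on an 8-tip tree; rate recovery on 500 simulated families on
a 128-tip tree; enrichment calibration on 500 no-signal categories; the
power experiment on 20 seeded default bundles; and chronogram recovery on
16-tip fixtures — sizes chosen so each property is measured with comfortable
Monte-Carlo margins while the whole suite stays quick to run. Every random
quantity flows from explicit seeds through hashed substreams
(`substream_seed()`), so pipeline outputs are byte-identical across reruns
and independent of family execution order; the package is single-threaded.
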