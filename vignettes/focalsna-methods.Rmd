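---
title: "Models and methods behind focalsna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind focalsna}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`focalsna` analyses focal-sampling observation data from a closed animal
group — typically a captive colony in which every individual is known —
and quantifies its social structure: how strongly pairs associate, how
many kinds of relationship the group maintains, whether individuals sort
by sex, age or dominance, who dominates whom, and which individuals
occupy central network roles. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions made where
the methodology left genuine choices open.

## The data model

A collection period consists of ten-minute focal follows (one focal per
individual per calendar day), a nearest-neighbour scan once per minute
(several IDs when neighbours are equidistant — each counted as a full
data point), and timed dyadic interaction events classified as
affiliative or aggressive with actor and receiver recorded, so
directionality is preserved. Partial focals (e.g. the animal was lost)
are retained with their actual duration; validation warns, rather than
errors, when a focal's scan count disagrees with its duration by more
than a configurable slack (default 2 scans). Ages are real-valued years
(days/365.25): node-level models use age as a continuous covariate and
integer truncation would only create ties.

## Association indices and directed networks

For every ordered pair (A, B) the association index is

$$w(A,B) = \frac{X}{Y_{AB} + Y_A + Y_B + X},$$

where `X` counts samples with A focal and B its nearest neighbour (or
the seconds A-as-focal interacted with B), `Y_A` the samples with A
focal and a different partner, `Y_B` the mirror image, and `Y_AB` — both
observed but not neighbours in the same sample — is structurally zero
under focal sampling and is carried explicitly so the code mirrors the
index's definition. The ratio controls for unequal sampling of the two
partners, which matters because observation effort is never exactly
balanced. Design choices worth knowing:

* **Interaction attribution.** `X(A,B)` counts only events in which A
  was both the focal and the actor toward B. Whether the original
  protocol also credited the focal's time as receiver is not
  determinable from the recording scheme alone, so
  `count_interaction_durations(..., include_received = TRUE)` exposes
  the alternative.
* **Dyads never co-sampled** get weight 0, not `NA`: downstream matrix
  methods (regression, permutation) need complete matrices. A warning
  reports how many such pairs exist.
* Individuals with no focal time remain in the network as isolates
  (with a warning), so the node set always equals the colony.

## Binomial-mixture social complexity

Each ordered dyad contributes a sample `(x, d)`: the index numerator and
denominator. The model assumes `x ~ Binomial(d, p_k)` where the latent
class `k` (a "relationship type") has frequency `q_k`. Fitting is by EM,
entirely in log space because duration-based trials are large. The
number of classes is chosen by the Integrated Completed Likelihood,
`ICL = BIC + 2E`, with `BIC = -2\ell + (2K-1)\log n` (the mixture's free
parameters: K strengths and K−1 frequencies; the criterion's parameter
count is not stated in the source methodology, so the free-parameter
count is used) and `E = -\sum_{ik} z_{ik}\log z_{ik}` the entropy of the
posterior classification matrix. ICL therefore prefers the model whose
classes are not only likely but cleanly separated. Social complexity is
the Shannon entropy of the selected class frequencies,
`H = -\sum_k q_k \log q_k`, bounded by `log K`.

Numerical choices: the first EM start is a deterministic quantile split
of the empirical `x/d` ratios (reproducible without a seed); the
remaining `n_starts - 1` (default 5 total) perturb it on the logit
scale. Convergence is a relative log-likelihood change below `tol`
(default 1e-8) within `max_iter` (default 1000); non-convergence returns
the best iterate with a warning and is typical only for over-specified
K. Duplicate `(x, d)` patterns are collapsed with multiplicity weights —
an exact reformulation that speeds the E step by an order of magnitude
when trial counts repeat. Ties in ICL (within 1e-6) break toward smaller
K. Degenerate fits (duplicated `p_k` within 1e-8, or `q_k < 1/n`) are
flagged but still scored; the entropy penalty makes ICL avoid them
naturally. `Kmax` defaults to 6, comfortably above the 3–4 classes such
colonies have been reported to support.

A caution inherited from the methodology: a published complexity table
for this kind of analysis prints H values inconsistent with applying the
entropy formula to its own printed class frequencies (likely computed
from unrounded parameters), so printed H values from the literature are
never used as numerical oracles here; all expectations in the test suite
are closed forms or recomputed quantities.

## Permutation inference

All significance testing uses node-label permutations: one random
relabeling applied simultaneously to rows and columns of the weight
matrix. This preserves topology — every individual's in/out strength
multiset and the multiset of edge weights — while breaking the
attribute-to-position association. p-values use the add-one rule
`(1 + \#\{|T_{null}| \ge |T_{obs}|\})/(1 + n_{perm})`, so they are never
zero and the test is exact-level. Defaults are 1000 permutations
throughout; every function takes a `seed` and is bit-reproducible.

* **Assortment.** Discrete attributes use the directed weighted
  mixing-matrix coefficient
  `r = (\sum_i e_{ii} - \sum_i a_i b_i)/(1 - \sum_i a_i b_i)`;
  continuous attributes use the edge-weight-weighted Pearson correlation
  of source and target values. Conjugating the matrix while holding
  attributes fixed is algebraically identical to dealing the attribute
  vector along the inverse permutation, which is how the null is
  computed. Sex is treated as discrete; age and dominance (David's
  score) as continuous.
* **MRQAP.** Coefficients are ordinary least squares on the vectorized
  off-diagonal dyads (diagonals excluded everywhere); significance is
  Dekker double-semi-partialling: each predictor's residual matrix
  (that predictor regressed on the others) is permuted by node
  relabeling, the model refitted, and the t statistic collected. The
  t statistic, not the raw coefficient, is compared — both are
  reported. The permutation scheme affects only p, never the estimates.
  An alternative reading of the source description ("randomising the
  residuals from the regression on each variable ... node degree")
  would add degree covariates; it is read here as a description of the
  residual permutation itself, which is the standard procedure.
* **QAP.** Pearson correlation between two per-node vectors with the
  node alignment permuted.

Within-row-and-column permutation, as sometimes described for these
randomisations, is implemented as node-relabeling conjugation: that is
the variant that actually preserves each individual's actor and
receiver totals; independent within-row shuffles would break the column
sums.

## Dominance

The win-loss matrix credits the actor of each aggressive event as its
winner — the recording protocol provides no finer outcome — measured in
interaction seconds by default (consistent with duration weighting;
`measure = "count"` is available and the report states which was used).
David's score combines each individual's win proportions with the
win rates of its opponents and sums to zero over the group. The default
dyadic proportion is the frequency-corrected `Dij` (the default of the
commonly used tooling); `Pij` is a flag. Hierarchy linearity uses
Landau's index on the dominance digraph with ties and unknown
relationships scored 0.5, plus the unknown-relationship correction
(`h' = h + 6u/(n^3 - n)`), and a right-tailed randomization test against
coin-flip tournaments.

## Node metrics and social roles

Weighted degree sums all incident edge weights (direction-agnostic).
Closeness accounts for edge direction (out-distances by default,
in-closeness by flag) with edge length `1/weight` — index weights are
affinities; paths need costs, a transform the methodology leaves
unstated. Raw closeness is normalized by `n - 1` on strongly connected
networks; when a node reaches only `r` of its `n - 1` alters its score
is `(r/(n-1)) \cdot (r/\sum d)`, a proportional penalty for
unreachability. Betweenness is computed on the symmetrized network
(its definition ignores direction) with fractional counting over
equal-length shortest paths, normalized as `2B/(n^2 - 3n + 2)` so a star
centre scores 1 at any n. Zero-weight edges are absent from all path
computations. Normalization uses each period's own `n`, so metrics are
comparable across periods of different colony size.

Role models regress each metric on all 8 subsets of
{sex, age, dominance} (Gaussian linear models, no interactions — the
candidate set mirrors how such analyses report main effects). Model
selection uses AIC with a parsimony reading of the "within 2 ΔAIC"
convention: the *most parsimonious* model within 2 units of the minimum
is selected; an intercept-only winner means no predictive factors, and a
tie between equally simple distinct models selects nothing. The literal
rule — lowest AIC at least 2 below the runner-up — can never fire when
the candidate set contains a nested superset of the best model, because
adding one useless Gaussian parameter costs at most 2 AIC units; the
parsimony reading is the standard resolution and the only one consistent
with such analyses reporting selected models at all.

Coefficient significance in the selected model comes from the
permutation null: the metric recomputed on each label-permuted network,
the model refit, and the observed coefficient compared two-sided to the
null coefficients. Because all three metrics are invariant under node
relabeling, recomputing on a conjugated network equals applying the
permutation to the observed metric vector; the implementation uses that
equivalence (exact, not an approximation), which reduces each null draw
to one linear solve. One honest caveat, verified by simulation in the
test suite: the permutation test itself is exactly calibrated (type-I
error ≈ α for a fixed model), but *selection-then-testing* is
anti-conservative — AIC prefers models whose coefficients happen to be
large, so among null datasets where a model is selected, significant
coefficients appear more often than α. This inflation is a property of
the two-stage procedure itself, not of the implementation.

Temporal stability stacks the three normalized metrics of the
individuals present in both periods into one vector per period
("stacked" mode, with one node permutation applied to all three blocks;
per-metric mode is a flag) and runs QAP. Stacked correlations are
dominated by between-metric scale blocks, so the raw r is high even for
shuffled alignments — only the permutation p, whose null shares the
block structure, is informative, and the package reports both.

## The synthetic colony generator

No raw observational data are released with the methodology this package
implements, so `synthetic_spec()`/`generate_dataset()` produce
focal-sampling datasets with planted, recoverable structure. Defaults
emulate the study design: 44 individuals (24 female), 35 observation
days, 18 ten-minute focals per day, one scan per minute, a 5% chance of
an equidistant-neighbour scan; `generate_colony()` adds a second, shorter
period (50 individuals — 28 female — over 20 days at 19 focals/day) with
42 conserved individuals whose latent dyad classes and dominance order
persist, so cross-period node metrics correlate as stable social roles
would.

Planted structure, per layer:

* **Relationship classes.** Every ordered dyad belongs to one of K
  latent classes with affinity `p_k`; the association default is the
  three-class mixture `q = (0.80, 0.15, 0.05)`,
  `p = (0.005, 0.05, 0.30)` — a majority of weak, a band of moderate,
  and a few strong relationships. Classes are allocated *within each
  focal's row* in proportions q (largest-remainder allocation), so
  every individual has the same total neighbour-choice propensity and
  the realized per-scan association probabilities stay in exactly K
  bands. A naive i.i.d. class draw (or a multiplicative similarity
  kernel on the affinities) makes row sums — and hence realized
  probabilities — vary continuously, and ICL then legitimately reports
  extra classes; the balanced-placement design is what makes the
  complexity dial and the assortment dial independent.
* **Assortment** is planted through class *placement*: within a row,
  dyads are ranked by `strength × standardized age similarity +
  Gaussian noise` and the high-affinity classes go to the top ranks
  (strength 0 recovers a uniform allocation; default strength 1 on age).
  High-affinity dyads thus connect similar-aged individuals, producing
  positive weighted age assortment without disturbing the mixture bands.
* **Dominance.** A latent total order; the higher-ranked member of a
  dyad is the actor of an aggressive event with probability `win_bias`
  (default 0.9, a strong hierarchy — low win biases at the default
  aggression rate of 0.1 events per focal minute leave too few
  informative contests to rank 44 individuals from a single season of
  events, which is itself a finding about sampling effort, not a useful
  default).
* **Interactions** arrive as Poisson counts per focal (defaults: 0.2
  affiliative and 0.1 aggressive events per minute) with geometric
  integer-second durations (means 30 s and 10 s) — memoryless bouts; the
  real ethogram records empirical durations whose shape the generator
  does not attempt to match.

What the generator deliberately does not emulate: enclosure geometry and
the section-rotation sampling order (focal order is random per day),
temperature gradients, cross-layer dependence beyond what shared
age-placement induces, observer error in IDs, and heterospecific
interactions. Passing recovery tests therefore demonstrates that the
pipeline's estimators see through sampling noise to planted structure —
not that real colonies satisfy the mixture model.

## Problem sizes and defaults used in validation

The test suite validates estimators on brute-force-checkable sizes
(5–15 nodes for path enumeration and recount oracles), calibrates each
permutation test on 1000 null simulations of 200 permutations, checks
mixture recovery on 20 replicates of the planted three-class design
(1800 dyads, 100 trials each), and runs the full pipeline at study scale
(44/50 individuals, 1000 permutations) once end to end, with planted-K,
assortment and dominance recovery asserted over 10 seeded replicates of
the first-period design. `scripts/acceptance.R` re-runs the study-scale
two-period pipeline from scratch and reports its headline quantities.

## Known limitations

* The binomial model treats duration-based samples as independent
  per-second Bernoulli trials; long bouts violate this, and
  duration-layer ICL consequently tends toward larger K than the
  association layer — a model-misfit signal, not a bug.
* David's scores from a single season of sparse aggression are noisy;
  the Dij correction shrinks but cannot remove this.
* MRQAP assumes a linear dyadic relationship on the index scale.
* The AIC parsimony rule and the selection-then-test caveat above mean
  reported "best models" are descriptive; their permutation p-values are
  exact only conditional on the model, not on its selection.
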