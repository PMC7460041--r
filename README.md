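# focalsna

Social network analysis of focal-sampling observation data from closed
animal groups — built for the kind of captive-colony study where every
individual is identifiable, observers run fixed-length focal follows
with per-minute nearest-neighbour scans, and dyadic interactions are
recorded with actor, receiver, category (affiliative/aggressive) and
duration.

From those records the package constructs three directed, weighted
networks per collection period (association, affiliation, aggression)
using a Simple Ratio Index whose joint-absence term is structurally zero
under focal sampling,

    w(A,B) = X / (Y_AB + Y_A + Y_B + X),        Y_AB = 0,

and analyses them with the standard toolkit of quantitative behavioural
ecology:

* **Social complexity** — dyadic association counts modelled as a
  K-class binomial mixture fitted by EM; K chosen by the Integrated
  Completed Likelihood (ICL = BIC + 2E, E the classification entropy);
  complexity summarised as the Shannon entropy H = −Σ q_k ln q_k of the
  class frequencies.
* **Assortment** — directed weighted assortativity for discrete (sex)
  and continuous (age, dominance) attributes, with significance from
  node-label permutations.
* **MRQAP** — network regression on vectorized dyads with Dekker
  double-semi-partialling permutation inference.
* **Dominance** — David's scores (Dij or Pij dyadic proportions) from
  aggression win-loss matrices, de Vries/Landau hierarchy linearity h′
  with a randomization test, and AIC selection of dominance ~ age + sex
  models.
* **Social roles** — weighted degree, direction-aware normalized
  closeness, and betweenness normalized as 2B/(n² − 3n + 2); role models
  over all subsets of {sex, age, dominance} with permutation-null
  coefficient inference; QAP tests of cross-season role stability.
* **Synthetic colonies** — a focal-sampling generator with planted
  relationship classes, age assortment, and a dominance order, plus
  ground truth for recovery testing (no raw data accompany the study
  design this package implements, so validation is simulation-based).

## Worked example

```r
library(focalsna)

g <- generate_dataset(synthetic_spec(seed = 7))   # default colony design
g$dataset
#> Focal-sampling dataset 'Summer2019': 44 individuals, 630 focals,
#>   6300 scans, 1939 interaction events

counts <- count_nearest_neighbour(g$dataset)
net <- simple_ratio_index(counts)
net
#> Weighted directed network (layer 'association', period 'Summer2019'):
#>   44 nodes, 1153 non-zero edges, mean weight 0.0205

sel <- select_binmix(dyad_samples(counts), Kmax = 6, seed = 7)
sel
#> Binomial mixture selection (ICL): selected K = 3, Shannon H = 0.6150
#>  K    loglik converged      BIC        E      ICL
#>  1 -11232.31      TRUE 22472.16    0.000 22472.16
#>  2  -4963.16      TRUE  9948.95    5.681  9960.31
#>  3  -3740.13      TRUE  7517.99  109.463  7736.92
#>  4  -3740.13      TRUE  7533.08  204.229  7941.54
#>  ...
```

The colony was generated with three planted relationship classes; ICL
recovers K = 3, and H = 0.615 summarises how evenly the three class
frequencies are spread (the ceiling for K = 3 is ln 3 ≈ 1.099 — most
dyads sit in the weak-association class, so H is well below it).

```r
age <- g$truth$attributes$age
assortment_test(net, age, kind = "continuous", variable = "age",
                n_perm = 1000, seed = 7)
#> Assortment by age (continuous): r = 0.5281, p = 0.000999 (1000 permutations)

W <- win_loss_from_aggression(g$dataset)
linearity_h(W, n_perm = 1000, seed = 7)
#> Hierarchy linearity: h' = 0.1431 (Landau h = 0.1001, 610 unknown dyads),
#>   p = 0.000999
```

Positive age assortment (r = 0.53) is detected at p ≈ 0.001 — the
generator plants it — and the aggression data show weak but significant
linearity: the planted hierarchy is real, but with ~0.1 aggressive
events per focal minute most dyads never meet in a contest (610 unknown
relationships), which keeps h′ low. `davids_score(W)` ranks the
individuals; `dominance_model()`, `role_models()` and
`temporal_stability()` continue the analysis, and `run_pipeline()` (or
the `inst/cli/focalsna` script) orchestrates every stage end to end,
writing GraphML networks and CSV reports with every seed logged.

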