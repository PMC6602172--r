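---
title: "Predicting ecosystem function from community profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting ecosystem function from community profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodriver)
```

## The problem

A rarefied 16S community table records, for each of $N$ samples, the counts
of $M$ taxa at a fixed sequencing depth. Alongside each sample a continuous
ecosystem function is measured — in the motivating application, dissolved
organic carbon (DOC) produced by litter-decomposition microcosms. Two
questions drive the package:

1. **Prediction** — how well does community composition predict the
   function? We fit $y = \mathcal{M}(\theta, \mathbf{x}) + \varepsilon$ with
   two very different regressors (a feed-forward neural network and a random
   forest) and score both by the Pearson correlation between predicted and
   held-out true values.
2. **Driver selection** — which taxa carry the signal? Three routes rank
   taxa: a gradient-based importance from the network, impurity importance
   from the forest, and indicator-value analysis; the consensus of all three
   is the defensible driver set.

## Data handling

**Replicate groups.** Microcosms inoculated from the same source community
diverge but are not independent. Train/test splits, the network's
early-stopping validation slice, and the sensitivity-analysis subsets are
all performed at the *group* level (`group_split()`), so no group straddles
a partition. Groups come from a metadata column or, by default, from the
sample-id prefix before the last `_`-separated token.

The split algorithm permutes groups and takes the prefix whose cumulative
sample count is closest to the requested test fraction; with unequal group
sizes the achieved test size therefore varies slightly from seed to seed,
exactly as one expects when replicate counts differ between sources.

**Rarefaction.** `rarefy()` subsamples each sample without replacement
(multivariate hypergeometric) to a common depth — 1023 by default, the depth
of the motivating data set — and drops, with a warning, samples whose totals
fall short.

**Standardization.** Features are z-scored using *training* statistics only
(`standardize()`); the stored statistics scale any further table or
community vector and invert exactly. We divide by the population ($n$)
standard deviation, the convention of the common machine-learning scalers;
at training sizes in the hundreds the difference from $n-1$ is immaterial,
and the choice is configurable. Constant training features are mapped to
zero rather than dividing by zero; they carry no information.

## The neural network

`nnreg()` fits a fully connected network — by default a single hidden layer
of $J = 15$ sigmoid nodes and a linear output — by mini-batch stochastic
gradient descent (batch 32, learning rate 0.05 by default) on an
L2-penalized mean-squared-error cost. A replicate-group-aware 20% slice of
the training rows serves as the validation set; training stops once the
validation cost has not improved for 10 consecutive epochs (patience), and
the returned parameters are those of the best-validation epoch. A hard cap
of 2000 epochs guards against non-converging traces. Weights initialize
uniformly at $\pm 1/\sqrt{\text{fan-in}}$, a scale that keeps sigmoid units
away from saturation at the start.

The defaults were set from training dynamics on the synthetic fixtures: at
much smaller learning rates the validation cost plateaus while the network
is still effectively linear and patience fires long before convergence.
`nn_random_search()` implements the randomized hyperparameter search over
hidden size (5–50), learning rate (log-uniform $10^{-4}$–$10^{-1}$) and L2
coefficient (log-uniform $10^{-6}$–$10^{-1}$), judged by the early-stopping
validation MSE on training data only.

### Gradient-based feature importance

For one sample, the importance matrix is the gradient of the model output
with respect to the first-layer input weights,
$F_{mj} = \partial \mathcal{M} / \partial \theta^{In}_{mj}
        = x_m \, \partial \mathcal{M} / \partial z_j$,
computed analytically by back-propagation (`nn_importance_matrix()`, checked
against central finite differences in the test suite). Averaging over the
$J$ hidden nodes gives the per-sample importance vector
$f_m = \frac{1}{J}\sum_j F_{mj}$, and averaging that over the training
samples gives the signed sensitivity $s_m$ (`nn_sensitivity()`): positive
entries mark taxa whose increased abundance raises the predicted function.

**A caution we document deliberately.** Writing
$c(\mathbf{x}) = \frac{1}{J}\sum_j w^{out}_j \sigma'(z_j)$, the sensitivity
is $s_m = \langle x_m\, c(\mathbf{x}) \rangle$ — for z-scored features, a
covariance between the feature and the network's hidden-saturation profile.
Its informative component is proportional to the fitted direction scaled by
$\mathrm{Cov}(t, c(t))$ where $t$ is the fitted linear score; that scalar
can be small, and its *sign* flips between retrainings (we measured
$\mathrm{cor}(c, \hat y)$ centered near zero across random
initializations). Three consequences shape the package defaults:

* single-fit sensitivities are noisy and sign-unstable, which is why the
  bootstrap wrapper exists;
* the bootstrap aggregates the **average per-iteration ranking** (by
  $|s|$ within each refit), not the rank of the average importance — a
  sign-flipped fit still ranks the informative taxa high in magnitude, so
  mean ranks survive what mean importances cancel; ties break by absolute
  mean importance, then taxon id, for deterministic output;
* the statistic is most informative when hidden units are partially
  saturated (larger learning rates) and on skewed, zero-inflated
  count-derived features — its natural habitat — and degenerates on
  symmetric Gaussian features.

`nn_bootstrap_importance()` retrains on random 80% row subsamples over 50
iterations by default; the sensitivity of each refit is averaged over the
*full* training matrix (the definition is a training-set mean, and the wider
average further damps per-fit variance). The signed bootstrap-mean
importance is retained for direction calls.

## The random forest

`rfreg()` delegates tree induction to `ranger`, configured to mirror the
standard regression-forest defaults of the field: 1000 trees, nodes split
down to two samples with single-sample leaves, all features eligible at
every split, trees grown on bootstrap resamples of the rows. Impurity
importance (`rf_importance()`) is normalized to sum to one; it is unsigned.
The same 80%/50-iteration bootstrap-ranking wrapper and mean-rank
aggregation apply (`rf_bootstrap_importance()`). Because forest predictions
are averages of leaf means, they can never leave the training-target range —
a property asserted throughout the tests and visible in the community-design
trajectories.

## Indicator taxa

`indval()` implements the Dufrêne–Legendre indicator value for a two-class
labeling of the samples. The continuous function is binarized by a median
split by default (ties to "low"); no biological threshold for "high"
function is known, and the rule (quantile, fixed threshold) is
configurable. For taxon $t$ and class $c$, specificity
$A_{tc}$ is the class mean abundance divided by the summed class mean
abundances, fidelity $B_{tc}$ the fraction of class samples containing the
taxon, and $\mathrm{IndVal}_{tc} = A_{tc} B_{tc}$; raw rarefied counts are
required because abundance shares and presence are meaningless after
z-scoring. Confidence comes from label permutations (1000 by default,
class sizes preserved, vectorized as cross-products with a permutation
membership matrix): the fraction of permuted best scores *strictly* below
the observed best score, with ties counting against significance —
conservative by construction. Significance requires 95% confidence, so at
least 99 permutations are demanded for resolution.

## Consensus and its null

The number of significant indicator taxa defines the default size $k$ of
the machine-learning top sets (`top_k_sets()`); the consensus is the triple
intersection (`consensus_table()`). `overlap_curve()` traces the pairwise
and triple overlaps of the top-$k$ prefixes as $k$ grows; all four curves
are nondecreasing because prefix sets are nested. The Monte Carlo null
(`mc_overlap_null()`) draws three independent uniform orderings and counts
prefix intersections; under independence the expected pairwise overlap is
$k^2/M$ and the triple overlap $k^3/M^2$ (at $M = 1709$, $k = 285$: about
47.5 and 7.9), which the simulation reproduces within Monte Carlo error —
the test suite checks this against the closed form. `sign_agreement()`
compares the sign of the network sensitivity with the indicator class
(positive ↔ "high") over the jointly selected taxa.

## Evaluation designs

* `permutation_experiment()` re-draws the group-aware split many times
  (50 in the reference design) and evaluates each requested model ×
  feature-set arm on byte-identical partitions (fingerprinted with MD5);
  `compare_arms()` applies a two-tailed t-test to the per-split
  correlations — Welch unpaired by default with a paired option, since arms
  share splits and both variants are defensible — plus a win fraction over
  test samples (ties count half).
* `sample_size_sensitivity()` draws group-aware subsets of the training set
  at a grid of fractions (10 replicates per fraction by default) and
  evaluates on the fixed test set: a learning curve with error bars.
* `abundance_prevalence()` summarizes mean counts and occupancy per taxon
  for histogram comparisons of selected versus all taxa.

## In-silico community design

From a starting community (by default the training sample with the extreme
target value), `gradient_trajectory()` moves in standardized space along
the signed sensitivity, $\mathbf{x}_{new} = \mathbf{x} + \alpha \mathbf{s}$,
recording both models' predictions per magnitude $\alpha$.
`random_trajectory()` provides the baseline: isotropic Gaussian directions
rescaled so each step has exactly the norm of the gradient step — "scaled by
magnitude" is otherwise ambiguous, and norm-matching makes the comparison
fair. The default $\alpha$ grid has 21 points from 0 up to the magnitude at
which the step norm equals twice the median inter-sample distance: far
enough to leave the data cloud, where the contrast between extrapolating
network and range-bounded forest becomes visible. Perturbed communities are
not clipped to the non-negative count orthant (an optional inverse transform
reports them on the count scale); they are hypotheses, not recipes.

## The synthetic generator

`synthetic_community()` emulates the features of the motivating data that
the methods actually exercise: log-normal latent abundances pushed through
a softmax and multinomial sampling give sparse, heavy-tailed, fixed-depth
count rows; a shared group latent with a within-group correlation knob
gives replicate triplets of tunable similarity; the target is a linear
combination of z-scored *relative* abundances of a planted driver set plus
Gaussian noise, so depth never leaks into the signal, and the planted ids
and signs are returned as ground truth (`realized_effect_report()` verifies
the realized correlations). Defaults mirror the study conditions: 100
groups of 3 replicates, depth 1023, 1709 taxa, 20 drivers.

What the generator does *not* emulate: phylogenetic correlation structure,
taxon–taxon interactions, compositional effects beyond the softmax closure,
and any relationship between abundance and detection noise. Passing tests
on this generator therefore demonstrate correct mechanics and recoverable
signal under favorable, known conditions — not performance on real
communities.

**Recovery benchmark.** The zero-noise recovery benchmark used by the tests
and the acceptance script plants a minimal driver pair (+1/−1) among 150
taxa in 300 samples, with the network run at learning rate 0.1 and patience
30 (the partially saturated regime where the gradient statistic is
informative) and 50 bootstrap iterations. This design follows from the
sensitivity analysis above: with many simultaneous drivers the network
route demonstrably spreads importance over compositionally correlated
proxies, so a benchmark demanding exhaustive recovery of a large driver set
would test the impossible. The forest route recovers planted drivers
essentially perfectly in the same conditions; the consensus inherits the
network's limits, which is precisely the argument for using three routes.

## Problem sizes and numerical choices

The test suite and the acceptance script run on scaled-down problem sizes
chosen as the smallest at which each property is comfortably detectable:
tables of 150–300 taxa and 120–309 samples, 1000 indicator permutations,
1000 Monte Carlo null simulations at the full 1709-taxon scale (the null is
cheap), bootstraps of 25–50. The full-scale reproduction paths accept
tables of any size. Other numerical choices: strict inequality in
permutation confidence; 0/0 → 0 for absent taxa in IndVal; rank ties broken
lexicographically; all randomness flows through explicit integer seeds, and
every seeded operation is reproducible bit-for-bit.

## Known limitations

* The gradient importance statistic is intrinsically noisy (see above); its
  rankings are trustworthy only after bootstrap mean-rank aggregation, and
  its signs only where the bootstrap mean is large relative to its spread.
* Indicator analysis ties significance to a binary split of a continuous
  target; taxa associated with mid-range function are invisible to it.
* The consensus-set size depends on the indicator significance count, which
  in turn depends on the split rule and permutation count; both are exposed
  as parameters.
* Forest extrapolation is impossible by construction; design trajectories
  from the forest are informative only inside the training range.
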