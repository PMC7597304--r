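---
title: "Antifragility as a predictor of robustness and evolvability in Boolean gene regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Antifragility as a predictor of robustness and evolvability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnaf)
```

## The problem

Boolean networks are the classic discrete model of gene regulation: each
gene is a binary node updated synchronously by a fixed logical function of
its regulators. The attractors of the update map — fixed points and limit
cycles — are read as cell types or cell functions, and the response of the
attractor set to a structural mutation defines two key evolutionary
properties. A mutant that preserves every original attractor is *robust*; a
mutant that exhibits at least one new attractor is *evolvable*. The four
combinations partition all possible responses:

| class | relation of mutant attractors $A'$ to original $A$ |
|---|---|
| not robust & not evolvable | $A' \subsetneq A$ |
| not robust & evolvable | incomparable ($A \not\subseteq A'$, $A' \not\subseteq A$) |
| robust & not evolvable | $A' = A$ |
| robust & evolvable | $A \subsetneq A'$ |

Deciding the class exactly requires enumerating all $2^N$ states twice,
which becomes infeasible for large $N$. The package implements both the
exact classification (for networks up to a configurable cap, default
$N \le 26$) and a predictor that avoids it: *antifragility*, a statistic of
the sampled dynamics under transient state-flip perturbations, whose
original-minus-mutant difference curve is fed to a small convolutional
classifier.

## Dynamics, attractors and basins

`boolean_network()` stores one truth table per node. Two bit conventions
are fixed package-wide because the literature never pins them down: node 1
is the least significant bit of the integer state encoding, and the first
listed input of a node is the most significant bit of its truth-table row
index. Nodes with zero inputs are legal constants (link deletion creates
them), self-inputs are allowed, parallel edges are not.

`find_attractors()` assigns every state exhaustively. Rather than tracing
states one by one in an R loop, it composes the vectorised successor map
with itself $N$ times, yielding $f^{2^N}$; since no transient is longer
than $2^N$, the image of every state under this map lies inside its
attractor, and the cycles are then traced only over those representatives.
The result is exact: basin sizes sum to $2^N$ by construction, which the
tests assert, and the whole analysis is cross-checked against an
independent per-state convergence oracle on hundreds of random networks.

The basin-size distribution is summarised by the normalized basin entropy
$H = -\sum_\rho p_\rho \log_2 p_\rho / N$ with $p_\rho$ the fraction of
state space draining into attractor $\rho$: 0 when one attractor absorbs
everything, 1 when every state is its own fixed point.

## Mutations

Four elementary structural mutations model genetic change while preserving
the node set (`mutation()`, `apply_mutation()`): adding a link, deleting a
link, re-pointing a link, and flipping one truth-table output bit. How
truth tables respond to arity changes is not determined by the biology, so
the package fixes an invertible convention: an added input becomes the most
significant row bit with the original table copied into its 0-slice and
seeded random bits in the 1-slice, and deletion projects onto the 0-slice
of the removed input. Under this pair of rules `delete(add(net)) = net`
exactly, which the tests verify; the unperturbed regime of an added
regulator leaves the node's function untouched.

`sample_mutants()` draws a cohort with the four kinds as equal as possible
(counts differ by at most one), rejecting duplicates at the level of the
*mutated network* in canonical form (inputs sorted, tables re-indexed), so
two syntactically different mutations producing the same function count
once. If a kind runs out of fresh mutants its remaining quota moves to the
other kinds.

## Emergence, complexity and the fragility measure

For an observation window of states, each node's *emergence* is the binary
Shannon entropy of its ON-fraction; the network emergence $E$ is the node
mean, self-organization is $S = 1 - E$, and complexity is

$$C = 4\,E\,(1 - E),$$

maximal ($C = 1$) at the change/regularity balance point $E = 0.5$ and zero
at both extremes. The external-perturbation protocol
(`perturbation_config()`) runs $2T$ synchronous steps; at every step whose
index is a multiple of the period $O$, a fresh uniform subset of $X$ nodes
is flipped *before* the update, and the window is the $T$ post-update
states at $t = T+1,\dots,2T$, discarding the transient. The fragility value
at intensity $X$ is

$$\oint = -(C - C_0)\cdot\frac{X}{N \cdot O},$$

where $C_0$ and $C$ are mean complexities of unperturbed and perturbed
runs over the same $s$ initial states. Negative $\oint$ means the dynamics
*gain* complexity under perturbation (antifragile), zero robust, positive
fragile.

Parameter defaults are the standard protocol for networks of this size
($N \le 26$): $T = 200$ steps (curves converge quickly in $T$; the
acceptance suite verifies stability under doubling $T$ at the Monte-Carlo
scale), $O = 1$ (most discriminating), $s = 1000$ initial states,
$X = 1,\dots,N$. When $2^N \le s$ the full state space is enumerated
instead of sampled. Time per fragility point is linear in $N$ at fixed
$(T, s)$; a full curve over $X = 1..N$ is therefore quadratic in $N$.

Three conventions here were genuinely open and are fixed as follows:
flip-then-update with post-update recording (a single unambiguous event
order); a fresh node subset at every perturbation event; and *common random
numbers* — initial states and flip draws depend only on the configuration,
never on the network, so an original and its mutants under one
configuration are compared on identical perturbation histories, removing a
large variance component from the difference curves.

`difference_curve()` interpolates both curves piecewise-linearly onto 30
evenly spaced normalized abscissae spanning $[1/N, 1]$ and subtracts mutant
from original, making curves from networks of any size commensurable;
30 points is the feature width consumed by the classifier. Linear
interpolation is the simplest scheme consistent with the curve's pointwise
construction; for $N = 30$ the grid coincides with the native one and the
operation is exact.

## The classification pipeline

`build_dataset()` assembles the labelled 30-point curves.
Robustness/evolvability labels are heavily imbalanced, so the training
portion is balanced by neighbour-interpolation oversampling
(`oversample()`): SMOTE equalises counts exactly; ADASYN allocates the
synthetic budget per minority point by the fraction of its neighbours in
other classes. Both retain every original row and synthesise only convex
combinations of same-class neighbours — properties the tests check
geometrically.

`build_cnn()` provides two 1-D convolutional architectures over the
$30 \times 1$ signal: *simple* (Conv, Conv+ReLU, Pool, Flatten, FC, Out)
and *complex* ((Conv+ReLU)×2, Pool, (Conv+ReLU)×2, Pool, Flatten, FC,
Out). Internals the architecture names leave open are package defaults,
all exposed as arguments: kernel width 3, valid padding, channels 16/32
(simple) and 16/16/32/32 (complex), max-pool width 2, a 64-unit ReLU
fully connected layer, softmax output, cross-entropy loss, Adam at
learning rate $10^{-3}$. No deep-learning backend exists in the target
environment, so forward, backward and Adam are implemented in the package
and the analytic gradient is verified against numeric differentiation in
the test suite.

`nested_cross_validation()` selects among 12 hyperparameter sets (batch
size 32/64/128 × SMOTE/ADASYN × simple/complex, 128 epochs): a stratified
75/25 outer split, $k = 4$ folds on the training portion, and per fold
three 67/33 inner splits of the *balanced* fold-training data scored by
one-vs-rest AUC (macro by default, since plain "AUC" underdetermines the
multiclass extension); the winner is retrained per fold on balanced data
and evaluated on the untouched, imbalanced test portion. Balancing before
the inner split deliberately replicates the original protocol even though
synthetic neighbours then leak across the split and inflate inner
validation scores; `balance_before_split = FALSE` gives the leak-free
variant. The outer split is stratified-random, not grouped by source
network; rows carry their network identifier so group-aware splitting can
be layered on, but cross-network leakage is present by default, as in the
protocol being replicated.

Evaluation (`evaluate()`) reports accuracy, the row-normalized confusion
matrix, per-class precision-recall curves with step-wise average precision
(no precision envelope), and the micro-average over all binarized
(example, class) decisions. The honest baseline under imbalance is the
random-classifier AP, which equals the positive-class prevalence
(`random_baseline_ap()`).

## What the synthetic data does and does not establish

Two generators stand in for curated biological models, which ship with
licensing and size constraints that keep them out of a self-contained
package:

* **Random NK networks** (`generate_rbn()`): $K$ distinct inputs per node
  drawn uniformly with self-inputs allowed, truth-table bits i.i.d.
  Bernoulli(0.5). They exercise every code path (dynamics, attractors,
  mutations, curves) and at $K = 2$ sit at the critical regime commonly
  used to emulate regulatory networks. They do *not* reproduce the
  in-degree heterogeneity, canalizing functions or modularity of curated
  biological networks, so class distributions measured on them quantify
  the pipeline's correctness, not biology.
* **Separable feature fixture** (tests): four class-mean curves with
  Gaussian noise ($\sigma = 0.05$) at realistic imbalance (60/200/90/30).
  A green CNN test on it establishes that selection, training and
  evaluation work and beat the prevalence/random-AP baselines on a
  learnable problem — not that antifragility differences from any
  particular network family are this separable.

## Numerical choices and degenerate inputs

* $0 \log 0 = 0$ in all entropies; basin probabilities of zero are dropped.
* Cramer's V drops all-zero rows/columns first and requires a 2×2-or-larger
  remainder; a table with an expected-zero cell cannot occur after that.
* `classify_change` is exact set comparison on canonical state sets — no
  tolerance is involved anywhere in classification.
* Probabilities in the cross-entropy are clipped at $10^{-12}$; softmax is
  computed with the max-subtraction trick.
* Max-pooling breaks ties toward the earlier position; odd trailing
  positions are dropped (floor division), matching 'valid' pooling.
* `difference_curve` extrapolates as a constant beyond the native $X/N$
  range (only reachable with custom `X_values` grids).
* Exhaustive enumeration refuses $N$ above the cap by name rather than
  guessing; classification across different node counts is an error, never
  an approximation.

## Limitations

* Exhaustive attractor analysis is memory-bound near the $N = 26$ cap
  (several integer vectors of length $2^N$); SAT/BDD-based attractor
  search is intentionally out of scope.
* Only synchronous, deterministic, binary dynamics are modelled — no
  asynchronous update, multi-valued logic, or SBML-qual import.
* The fragility statistic is Monte-Carlo: values carry
  $O(s^{-1/2})$ noise, and comparisons should keep the common-random-number
  pairing the package applies by default.
* Training the full 12-set grid at 128 epochs on a 37,000-row dataset is a
  multi-hour CPU job in this pure-R implementation; the package keeps all
  sizes configurable and its own test suite runs reduced grids.
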