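---
title: "Tensor Markov fields: models, verification and inference choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tensor Markov fields: models, verification and inference choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensorMRF)
```

## The model

A tensor Markov field is a Markov random field whose variables carry a
double index: `X_ih` is variable `i` observed in layer (context) `h`.  The
vertex set of the resulting multilayer graph is the full grid of `N`
variables times `L` layers, and undirected edges may run within a layer
(e.g. gene--gene co-expression) or across layers (e.g. a miRNA regulating a
gene's transcript).  Three mathematically equivalent descriptions of the
same dependency structure appear throughout the package:

* a **multilayer graph** (`MultilayerGraph`): vertices plus a neighbourhood
  law;
* a **Gibbs field** (`GibbsField`): strictly positive clique potentials
  `phi_C`, inducing `P(omega) = prod_C phi_C(omega_C) / Z` with the product
  over *all* cliques -- the empty set and singletons included, which is what
  makes the equivalence with the Markov property work;
* a **4-index hypermatrix** (`Hypermatrix`): `A[i,j,h,k] = 1` when
  `(i,h)--(j,k)` is an edge, with the symmetry `A[i,j,h,k] = A[j,i,k,h]` and
  an all-zero bi-diagonal `A[i,i,h,h]`.

The package's purpose is to make the equivalences *executable*: every
theorem connecting these descriptions is a function whose claim can be
checked numerically on enumerable examples.

## Exact machinery and its guards

All exact operations (partition function, joint tables, conditionals,
sampling) enumerate the configuration space `|S|^(N x L)` and refuse spaces
larger than `maxConfigs` (default `2^20`) rather than silently
approximating.  Products of potentials accumulate in log space, so fields
with many cliques cannot underflow.  An approximate single-site heat-bath
sampler (`gibbsSample`) exists for larger fields, with a default burn-in of
`100 * nV` sweeps; it generates fixtures and is never used as an exactness
oracle, because its draws form a Markov chain rather than independent
samples.

The Markov property itself is a test: the local characteristic of a vertex,
computed *only* from the potentials of cliques containing it, must equal the
conditional distribution extracted from the full joint table.  Both suite
and acceptance script run this comparison over dozens of random fields, and
the observed deviations sit at machine precision (~1e-15), far below the
1e-10 contract.

## The Moebius construction

Given a strictly positive joint `P` and a designated default label ("0"),
the candidate potential of a subset `sigma` is the inclusion--exclusion
product over all `zeta` inside `sigma` of `P(X_zeta = x_zeta, rest =
default)` raised to `(-1)^(|sigma| - |zeta|)`.  Two conditions make these
genuine clique potentials, and both are verified mechanically:

* **Factorisation** (`verifyFactorization`): the product of the candidate
  potentials over every subset of the vertex set telescopes back to `P`,
  for *any* strictly positive `P` -- graphical or not.  Sign bookkeeping is
  integer and accumulation is in log space; the check enumerates `2^nV`
  subsets and is guarded at 10 vertices.
* **Clique support** (`verifyCliqueSupport`): when `P` is Markov with
  respect to a graph, `f_sigma` is identically 1 on every non-clique
  `sigma`.  The test reports the worst offending subset, which is also a
  useful diagnostic when `P` carries an interaction the graph does not draw.

Positivity is the theorem's hypothesis, so it is enforced with an explicit
floor (`min P > 1e-300`) and a loud error -- never smoothed, because
smoothing would mask genuine violations.  Changing which label plays the
default changes individual `f_sigma` values but never the reconstructed
product; the suite checks this with both binary defaults.

Default tolerances follow the arithmetic: 1e-8 for the exact-arithmetic
identities (observed error ~1e-13 on 8-vertex tables), and 1e-6 for
classifying conditional independence on exact joints (observed deviations
are either ~1e-15 for true CI or >1e-3 for planted edges, so the margin is
wide on both sides).

## Conditional independence and I-maps

CI on exact joints is always evaluated in the cross-multiplied product form
`|P(u,v,S) P(S) - P(u,S) P(v,S)| / P(S)^2`, never by materialising
conditional tables, which avoids amplifying error through small
denominators.  The minimal I-map of a positive joint
(`ciGraphFromJoint`) draws an edge exactly where the pair is *not* CI given
all remaining vertices.  (The printed definition in the source literature
would connect conditionally *independent* pairs; that contradicts
minimal-I-map semantics and the standard reading is implemented.)

`isIndependenceMap` checks the global Markov property.  Exhaustive
enumeration of disjoint subset triples costs `4^nV` assignments, so it is
used up to 6 vertices (4096 assignments); above that the function switches
to a documented reduced check -- all pairwise relations given the rest plus
all single-vertex separators -- which is what the pairwise-implies-global
theorem for strictly positive measures licenses.  The 8-vertex acceptance
scenarios therefore run the reduced mode; the exhaustive mode is exercised
on 6-vertex fields in the unit suite.

The count of pairwise tests is `choose(NL, 2)`, one per unordered vertex
pair (the source text's `M = NL2` is typographically ambiguous; the
sigma-algebra construction it describes implies the binomial count).

## Mutual-information inference

The information-theoretic route from data to structure is: discretise,
estimate all pairwise mutual informations, mask the bi-diagonal, threshold.

* **Estimator**: plug-in (maximum-likelihood) MI in bits.  No bias
  correction by default -- the raw functional is what the thresholding rule
  is defined on; the estimator sits behind one internal function and is
  trivially replaceable.
* **Discretisation**: equal-frequency (rank) binning, default 10 bins, ties
  broken by stable sample order; codes are invariant under strictly
  increasing transforms, which is the right property for expression-like
  data.  Columns that are already discrete (at most `nBins` distinct
  values) are relabelled, not re-binned.
* **Bi-delta masking**: `I[i,i,h,h]` is forced to zero (self-information is
  not an edge), but the *same variable in two different layers* is a
  legitimate pair -- a gene and its own transcript in another omic layer may
  carry real mutual information.
* **Threshold**: the Heaviside rule is strict (`> i0`), so an entry exactly
  at the threshold is excluded and raising `i0` can only remove edges.  The
  threshold itself can be fixed, or chosen as the `(1 - alpha)` quantile of
  a permutation null that pools MI values across all column pairs under
  independent sample-order permutation (default 100 permutations,
  alpha = 0.05).

### What the generator emulates, and what passing tests do not show

`makeScenario` plants a random multilayer graph (defaults: N = 4 variables,
L = 2 layers, binary labels -- a 256-configuration space enumerable in
microseconds; intra-layer edge probability 0.25, inter-layer 0.15, the
inter-layer coupling sparser as in regulatory multi-omics), equips each edge
with a pairwise potential whose log entries are drawn from
`[-s, -0.2 s] U [0.2 s, s]` at strength `s = 1` (bounded away from zero so
no planted edge is degenerate), and draws exact independent samples from
the joint.  `gaussianize` maps labels to real levels plus Gaussian noise to
emulate continuous expression data.

The generator does **not** emulate negative-binomial count noise,
library-size effects, batch structure or missingness.  Passing recovery
tests on these scenarios shows the estimator-threshold pipeline is correct
and calibrated under clean conditions; it does not certify performance on
real RNASeq data.

A further honest limitation is visible in the sampled-data recovery
numbers: MI thresholding is a *relevance network* method.  A chain
`u -- w -- v` with two strong couplings gives `u, v` a mutual information
well above any independence null, so the inferred edge set systematically
contains indirect-path false positives; conversely a pairwise potential
whose log-odds ratio happens to be near zero is statistically invisible at
moderate `n` even though its entries are individually bounded away from
unity.  On the default scenarios at n = 2000 the median F1 against the
planted graph is about 0.7, and even an oracle threshold (the best possible
`i0` per dataset, chosen with knowledge of the truth) yields a median near
0.89 -- the residual gap is inherent to thresholding marginal MI without a
conditional-independence correction, which is exactly the gap the
exact-joint route (`ciGraphFromJoint`, recovery rate 1.0 on the same
scenarios) closes when the joint is available.

## Tensor summaries

The hypermatrix with declared index roles *is* the multilayer adjacency
tensor; contractions with all-ones tensors are implemented directly and no
unit tensor is materialised.  `multidegreeCentrality` is the full
contraction `K[i] = sum_{j,h,k} A[i,j,h,k]`; each undirected edge
contributes one unit at each endpoint, intra- and inter-layer alike (the
index conventions admit a double-counting variant; the plain contraction is
used and documented).  `layerPairDegree` gives the per-layer-pair split,
and the identity `K = sum_{h,k} k(h,k)` holds exactly by summation order,
as does `sum_i K[i] = 2 |E|` for binary tensors.

## Numerical and design notes

* Vertex ids are `(h-1) * N + i`; configurations are little-endian mixed
  radix, so all index arithmetic is exact doubles up to the `2^20` guard.
* Edges are stored canonically (smaller id first, rows sorted, deduplicated)
  so that serialisations diff cleanly across runs.
* Clique size is reported as vertex count (a triangle is a 3-vertex clique),
  not the offset-by-one naming some figures in the field use.
* All generator randomness derives from one scenario seed through named
  substreams (graph / potentials / sampling / noise), so components can be
  regenerated independently without disturbing each other.
* Problem sizes in the test suite (fields of 4--9 binary vertices, 100
  recovery scenarios, 20 sampled-data replicates at n = 2000, 1000 random
  hypermatrices) were chosen so every theorem is exercised across distinct
  random structures while the whole suite stays enumerable exactly.

## A worked example

```{r}
sc <- makeScenario(nSamples = 2000, seed = 11)
sc

# the three equivalent views of the planted structure
edgeSet(scenarioGraph(sc))
verifyFactorization(scenarioJoint(sc))$maxRelError
verifyCliqueSupport(scenarioJoint(sc), scenarioGraph(sc))$pass

# exact-route recovery
sameGraph(ciGraphFromJoint(scenarioJoint(sc)), scenarioGraph(sc))

# sampled-data route
fit <- inferNetwork(scenarioSamples(sc), alpha = 0.05, nPerm = 100, seed = 11)
fit$threshold
edgeRecoveryF1(scenarioGraph(sc), fit$graph)

# tensor summaries of the planted structure
multidegreeCentrality(hypermatrixFromGraph(scenarioGraph(sc)))
```
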