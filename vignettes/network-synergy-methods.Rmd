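---
title: "Methods: drug-combination calls from signed directed regulatory networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drug-combination calls from signed directed regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regnetsyn)
```

## The model and its assumptions

`regnetsyn` treats a drug combination as two perturbations of one signed
directed network whose nodes are protein/gene targets and whose edges are
directed regulatory relations — activation and expression (positive),
inhibition and repression (negative). The model makes four substantive
assumptions:

1. **Directed propagation.** Drug effect enters at the targets the drug binds
   (immediate nodes, sign +1 for activation/upregulation, −1 for
   inhibition/downregulation) and flows only along edge direction.
2. **Attenuation.** Each hop divides the transmitted intensity by an
   attenuation coefficient δ ≥ 1; a path of `hop` edges contributes
   `±1/δ±^hop` to the terminal node's intensity of action (IA), with δ₊ used
   for positive-net-sign paths and δ₋ for negative ones. The coefficient is
   chosen by the path's *net* sign, not per edge; under the blocking rule
   below the net sign equals the terminal edge sign, so the alternative
   per-edge mixing of δ's only differs on paths that cannot occur.
3. **Blocking.** Negative regulation can abolish downstream signaling, so a
   path whose latest edge is negative is terminal, and an immediate node the
   drug inhibits does not forward signal at all. Blocking is per path, not
   per node: a node reached negatively by one path still relays signal it
   receives on a different positive path. A global node knock-out would make
   IA depend on evaluation order; the per-path rule keeps IA a well-defined
   sum over simple paths.
4. **Proximity ≈ interaction.** The closer two effect sets lie in the
   network, the more their effects interact. Same-sign sets close together
   reinforce (synergy); a positive set close to the partner's negative set
   cancels (antagonism).

IA sums over *simple* directed paths (no repeated node) of at most `hop_max`
edges from every immediate node; multiple paths into the same node add.
Nodes partition into the positive set (IA > 0) and negative set (IA < 0);
IA = 0 nodes — untouched or exactly cancelled — are negligible for the
analysis. The IA-vs-0 comparison is exact, not tolerance-based:
contributions are sums of exact binary reciprocals, and a tolerance would
silently reassign set membership. Callers wanting a dead zone can filter the
`ia` vector themselves.

## Set distances and the call

For node sets *I*, *J* the relative network distance is the symmetrized mean

d(|I,J|) = ½ [ (1/n_I) Σ_i (1/n_j) Σ_j d(i,j) + (1/n_J) Σ_j (1/n_i) Σ_i d(j,i) ]

where d(i,j) is the directed, unweighted (hop-count) shortest path on the
*full* network — edge signs and the IA `hop_max` do not restrict it — and the
inner sums run only over reachable partners: n_j is the number of *J* nodes
reachable from i, n_I the number of *I* nodes reaching anything in *J* (and
symmetrically for the second term). "Regulated by" is read as directed
reachability, not adjacency; observed distances well above 2 require
multi-hop paths, and averaging infinities would otherwise leave most set
pairs undefined. Three deliberate choices at the margins:

* **One-sided reachability.** If only one direction's bracket term is
  defined, the distance is that term alone; if neither, the distance is
  undefined (`NA`). Discarding a defined direction would throw away
  information; substituting a finite pseudo-distance would fabricate calls.
* **Shared nodes.** A node in both drugs' sets contributes zero
  self-distances to the averages — shared targets legitimately pull sets
  together.
* **Undefined propagation into d₊/d₋.** `d₊ = d_pp − min(d_pm, d_mp)` and
  `d₋ = d_mm − min(d_pm, d_mp)` take the min over the *defined* reverse
  distances; if both are undefined, or the forward distance is, the result is
  `NA` and the call is indeterminate.

The call is synergism iff d₊ < 0 and d₋ < 0; antagonism iff d₊ > 0 or
d₋ > 0; anything else (both zero, any `NA`, or the mixed case d₊ < 0 with
d₋ = 0 where neither rule fires) is indeterminate. For ranking (ROC), the
package uses `score = −max(d₊, d₋)`; any monotone score consistent with the
sign rules would give the same dichotomous calls, and this one is the least
committal: it is positive exactly when both relative distances are negative.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `delta_pos` (δ₊) | 1.5 | per hop | fitted optimum on labeled data; ≥ 1 so propagation attenuates |
| `delta_neg` (δ₋) | 1.1 | per hop | fitted optimum; negative regulation decays more slowly |
| `hop_max` | 2 | hops | balances information capture against the exponential growth of overlapping downstream effects |
| DE: NP/F/CR/Gmax/ε | 50 / 0.6 / 0.9 / 100 / 10⁻⁶ | — | standard DE/rand/1/bin control settings |
| DE bounds | [1, 3] per δ | — | δ < 1 would amplify; 3 comfortably brackets plausible optima |

The DE implementation is classical rand/1/bin: uniform initialization in
bounds, mutation `v = x_r1 + F(x_r2 − x_r3)` with three distinct partners,
binomial crossover with one forced dimension, clipping to bounds, greedy
selection with **ties keeping the incumbent** (the objective — accuracy on a
finite pair set — is a step function, and replacing on ties would random-walk
the population across plateaus). ε is applied to the improvement of the best
fitness over a 10-generation window; with a constant landscape this stops at
generation 11. Fitness counts indeterminate calls as errors, so the
optimizer cannot earn accuracy by refusing to classify.

## What the synthetic generator emulates — and what it does not

`generate_network()` draws a sparse directed G(n, p) graph with
predominantly positive edges (`positive_edge_frac = 0.7`; pathway-derived
regulatory relations are mostly activating). `generate_combination()` plants
a gadget realizing the two canonical topology regimes: each drug activates
half its targets (positive cluster) and inhibits the rest (negative cluster,
single nodes because of drug-level blocking). For synergy, same-sign
clusters are joined by 1-hop positive chains while cross-sign clusters are
connected only through relay chains of `cluster_separation` (default 4)
hops; for antagonism the roles swap, with the positive–positive relay chain
2 hops longer to absorb the 2-hop propagation leak out of an activated
cluster. Background edges are confined to non-gadget nodes, which is what
*guarantees* the ≥ `cluster_separation` separation rather than merely making
it likely. Default sizes: 60 nodes, edge probability 0.02, 4 targets per
drug.

Consequences for interpretation: a green planted-recovery test establishes
that the pipeline turns engineered proximity structure into the intended
call — it says nothing about real pathway topology. The generator does not
reproduce KEGG degree distributions, pathway sizes, hub structure, shared
targets between drugs, or label noise; real drug-pair accuracy must be
established on real data. Planted instances need `targets_per_drug ≥ 2`
(both clusters non-empty); requesting 1 is an error rather than a silently
different design.

## Numerical and degenerate-input choices

* Shortest paths, centralities, and graph containers come from `igraph`;
  path enumeration, IA, set distances, DE, and ROC are implemented in the
  package and verified in the test suite against independent oracles
  (exhaustive unpruned path enumeration, a hand-rolled BFS plus literal
  double loop, and pairwise concordance counting).
* The centrality screen for key targets uses a *strict* above-the-mean test
  on degree, betweenness, and closeness: "higher than average" read
  literally, which also makes vertex-transitive graphs return the empty set
  deterministically. Closeness on disconnected graphs is computed within
  each component (the standard definition); the mean is over all nodes, and
  isolated vertices (undefined closeness) are dropped from the mean and can
  never pass. Small components have inflated closeness under this
  definition, so the screen is most meaningful on a dominant connected
  component.
* ROC-AUC sweeps thresholds over the observed scores and integrates by
  trapezoid, which equals Mann–Whitney concordance with ties counted ½.
  Pairs with `NA` scores are excluded with a warning; single-class inputs
  give `NA`, not an error.
* Duplicate edges across pathways are merged (provenance concatenated);
  multiplicity is deliberately not used as an edge weight. At most two edges
  per ordered pair, one per sign.
* All TSV interfaces are UTF-8, header-rowed, `#`-commented; `NA` is the
  undefined-value sentinel.

## Known limitations

* Calibrating two parameters on a step-function objective gives plateaus,
  not a unique optimum; the reported coefficients are a plateau
  representative, and grid search is provided as the honest picture of the
  surface.
* IA is a path-count heuristic, not a dynamical model: no saturation,
  feedback, or time course; opposite-sign contributions can cancel exactly.
* The indeterminate class is a modeling outcome (undefined distances) but is
  scored as an error, which penalizes sparse or disconnected inputs.
* Identifier matching is exact and case-preserving; mapping between gene
  symbol / KEGG / UniProt namespaces is the caller's responsibility.

The bundled reference fixture (`inst/extdata/reference_pairs.tsv`) stores,
for 11 drug combinations, the four set distances under the package's
`d_pp/d_mm/d_pm/d_mp` column convention together with reference relative
distances and actual outcomes; the acceptance script and tests recompute the
relative distances, calls, confusion counts, and accuracy from it at run
time. No empirical claim is made in this vignette that those tests and
`scripts/acceptance.R` do not themselves compute.
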