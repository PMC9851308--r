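---
title: "Lipid species networks and enzymatic dysregulation enrichment"
author: "lipidnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lipid species networks and enzymatic dysregulation enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidnet)
```

# The problem

Lipid enzymes are *multispecific*: one enzyme catalyses the same class-level
transformation (say, the acyl transfer LPI + acyl-CoA → PI) across many
fatty-acyl compositions. A change in such an enzyme's activity therefore does
not show up as a single differential lipid but as a coordinated shift across
many substrate–product pairs of one class reaction. `lipidnet` builds a
dataset-specific lipid species network from curated class-reaction templates,
scores every species-level reaction for dysregulation between two sample
groups, and searches the reaction (hyper)network for a connected, maximally
dysregulated subnetwork — a mechanistic hypothesis for which enzymatic step
changed.

# The data model

Lipid species are parsed from shorthand nomenclature. A *sum species*
(`PC(34:1)`) records only total carbons:double bonds[;hydroxylations]; a
*molecular species* (`PC(16:0_18:1)`) resolves the individual chains.
sn-positions are deliberately not modelled: chains form an unordered
multiset, which matches the resolution of routine lipidomics and of the
class-reaction rules below. Classes live in a registry
(`defaultClassRegistry()`: abbreviation, headgroup, backbone, number of acyl
positions, category); the bundled registry covers 17 common
glycerophospholipid, lysophospholipid, glycerolipid and sterol-ester classes
and is a curated subset, not a complete nomenclature.

Class reactions (`defaultClassReactions()`) are multispecific templates in
four categories — headgroup modification (PS ↔ PE), headgroup
addition/removal (DG ↔ PA), fatty-acid addition/removal (LPC ↔ PC), and
lipid merging (PA + PG ↔ CL) — each with database and gene cross-references.
Cofactors (acyl-CoA, CoA) are implicit: only lipid participants are recorded
and the transferred acyl is resolved at species level. Live database parsing
is out of scope; the TSV dialect is the contract, so a site-specific curation
can be dropped in.

# Network extension

Rules are evaluated on *molecular candidates*. A molecular species is its own
candidate; a sum species is expanded against a fatty-acyl pool
(`defaultAcylPool()`: all even chains C12–C24 with 0–6 double bonds, no
hydroxylations, overridable globally or per class) into every chain multiset
with exactly the observed sum composition. A sum species with no valid
expansion is kept as an isolated node and reported. Two measured species are
connected iff at least one candidate pair supports the rule:

* headgroup change: identical chain multisets;
* fatty-acid addition/removal: one multiset contains the other, the
  single-chain difference is the *transferred acyl*;
* merging: the substrates' chains union to the product's (and all
  participants must be measured — networks are dataset-specific);
* fatty-acid rules (elongation +2C, desaturation +1DB,
  hydroxylation/oxidation +1OH) connect same-class species differing by one
  rule application on one chain. These do not occur on complex lipids
  directly, so the edges are *heuristic*: they improve connectivity but are
  score-penalised;
* ether conversion (optional, heuristic): same class and sum composition,
  different ether bond. Ether sum species are not expanded unless the pool
  itself carries ether chains.

Because several expansions of the same sum pair can support a rule with
different transferred acyls, a species reaction stores the full set of
supported transferred acyls. Reaction identifiers are content-derived
(`classReaction|substrates>products` with sorted participants), so identical
inputs always give identical networks.

```{r example-network}
net <- buildSpeciesNetwork(c("LPI(18:1)", "PI(38:5)", "LPC(18:0)",
                             "LPC(18:1)", "PC(34:1)"))
net
transferredAcyls(speciesReactions(net)[["FAAR_LPI_PI|LPI(18:1)>PI(38:5)"]])
```

# Scoring and enrichment

The *reaction network* has species reactions as nodes; two nodes are joined
iff they share a class reaction or a lipid. Heuristic rules are given
rule-level class-reaction ids (`FA:desaturation`, `ether_conversion`), used
uniformly both for this edge rule and when counting distinct class reactions
in the objective — consistent with their stated purpose of increasing
connectivity.

For a reaction with substrates $S$ and products $P$ and abundance matrix
$L$, the group-wise substrate–product change is either the absolute
difference (mean over the group's samples of mean product minus mean
substrate abundance) or the relative change (mean over samples of the
geometric-mean product/substrate ratio); the mean/root corrects for
reactions with several participants. The node score is
$|\Gamma^{D} - \Gamma^{C}| / |\Gamma^{C}|$, and heuristic reactions receive
a fixed score (default −1) so the search prefers genuine class reactions.
The default mode is *relative*: it is unit-free, invariant to per-sample
scaling (so normalisation constants cancel), and consistent with the
per-sample reaction-ratio analysis. In absolute mode a vanishing control
change is an error; in relative mode the denominator is floored at
$\varepsilon = 10^{-12}$, keeping scores non-negative as the optimisation
assumes.

A subnetwork $V^*$ is scored by
$o = \sum_{v \in V^*} \mathrm{Score}(v) \,/\, (|V^*| \cdot p \cdot
|\mathrm{CR}(V^*)|)$ where $\mathrm{CR}(V^*)$ is the set of distinct class
reactions among its nodes and $p > 0$ a parsimony penalty (default 1):
solutions explained by few class reactions are favoured.

The search runs independently per connected component, starting from a
random connected seed of `minSize` nodes. Each iteration enumerates all
legal moves — add a neighbour, delete a node keeping connectivity and the
size floor, or substitute a node for a neighbour — and applies the best
improving one (ties broken by lexicographic reaction id for
reproducibility). At a local optimum a random move is drawn and accepted iff
$\exp((o_{n-1}-o_n)/(-T)) > U(0,1)$ with $T = T_0\,\alpha^{\,n}$; a rejection
ends the run, as does move exhaustion or the iteration cap, and the best
state seen is returned. Defaults: $T_0 = 1$, $\alpha = 0.95$, size bounds
3–15, iteration cap $10^5$. Since the choice of seed set is open, the search
is restarted from independent random seeds (default 5) and the best result
kept; a conventional always-stochastic annealing variant is available behind
`alwaysStochastic`. On exhaustively enumerable networks (≤ 12 nodes) the
default configuration attains the brute-force optimum in ≥ 95 % of runs
(see the test suite).

## The empirical p-value, and what it is not

The subnetwork objective is compared against `nPvalueSamples` random
*unconnected* reaction sets with sizes uniform in the same bounds, scored
with the identical objective (including the class-reaction penalty):
$p = (1 + \#\{o_{\mathrm{sampled}} \ge o_{\mathrm{observed}}\}) / (n + 1)$.
The pseudocount keeps $p > 0$. This quantifies how much better the
connected, mechanistically coherent solution scores than equally sized
non-mechanistic reaction sets. It is **not** a calibrated frequentist test:
the observed value is an optimum while the reference draws are not, so even
on null data (no group difference) the p-value concentrates near its
$1/(n+1)$ floor. It should be read as a relative quality index of the
returned subnetwork, not as a false-positive-rate guarantee.

# Composition analyses

`reactionRatios()` computes the per-sample geometric-mean product/substrate
ratio of every species reaction (its group mean equals the relative
substrate–product change, a consistency the tests assert); densities per
condition can be drawn from the returned table with any plotting layer.
`nodeStatistics()` gives per-lipid log2 fold changes (on group means), Welch
tests (on log2 abundances — fold change and test deliberately live on the
same multiplicative scale) and Benjamini–Hochberg q-values.

`moietyFeatures()` decomposes the lipidome into abundance-weighted
substructure features — headgroup, backbone, individual fatty acyls, sum
chain length, sum double bonds, sum hydroxylations — where feature value =
Σ lipids abundance × occurrence; acyl occurrences count chain multiplicity,
and optional pair features multiply the two occurrences within a lipid. Sum
species contribute no acyl features. The published glycan-substructure
weighting this mirrors is not spelled out in full detail anywhere we could
implement from, so this occurrence-weighting is a documented stand-in and
may diverge from that method in corner cases. `moietyDiscrimination()`
standardises the features (constant columns are fixed at coefficient 0) and
fits an L2-regularised logistic regression of group membership
(`glmnet`, ridge, small fixed λ = 0.01) whose ranked coefficients order the
substructures by discriminative weight; the regression is descriptive
ranking, not inference.

# The synthetic-data generator

`simulateLipidome()` emulates a two-group knockout-style experiment with a
planted multispecific dysregulation. Defaults define the study conditions:
classes LPI/PI/LPC/PC with 8/22/8/22 species (≈ 60 lipids), 15 + 15 samples,
i.i.d. log-normal abundances with per-lipid log-means uniform in [3, 6] and
log-sd 0.25 (a standard heavy-tailed intensity model), and an 8× effect on
the LPI ↔ PI acyl transfer restricted to transferred acyls with ≥ 20 carbons
and ≥ 4 double bonds — the arachidonoyl preference of an MBOAT7-like
acyl-transferase.

Chain sampling mirrors glycerophospholipid biology: lyso species draw from a
saturated/monounsaturated sn-1-like pool; diacyl species pair an sn-1-like
chain with an sn-2-like chain from a pool of common sn-2 acyls (16:0, 18:1,
18:2 and the arachidonate/EPA/docosa-PUFA family). Sum-species expansion for
simulated data uses exactly the union of these generating pools: a wider
pool would propose molecular candidates that cannot occur in the simulated
experiment. This reproduces the defining property of the knockout scenario —
reactions between lyso and diacyl inositol lipids are essentially only
possible for long polyunsaturated transferred acyls — which is what makes
the acyl preference identifiable at all.

The generator plants the effect by multiplying the product species of every
qualifying network edge in the case group (or dividing substrates), so the
ground truth is by construction a subset of the network's edges. What the
generator does *not* emulate: instrument noise models, missingness,
correlated lipid co-regulation, isotope effects, and drift — so green tests
show the method recovers a planted multispecific mechanism under clean
conditions, not that it is robust to all real-data pathologies.

```{r simulate, eval = FALSE}
sim <- simulateLipidome(simulationSpec(seed = 1))
res <- enrichNetwork(sim@experiment, sim@network,
                     enrichmentConfig(nPvalueSamples = 999), seed = 2)
res
bestSubnetwork(res)
```

# Numerical and design notes

* Problem sizes in the test suite are chosen to keep the full suite within a
  few minutes at one core: formula oracles run on 1000 random 5-lipid
  instances; search optimality on 100 networks of 6–12 nodes against
  exhaustive enumeration; null behaviour on 200 reduced simulations
  (36 lipids, 8 + 8 samples); recovery on 50 replicates at the full default
  conditions.
* Strict improvement uses a $10^{-12}$ tolerance; deletion feasibility is
  decided by breadth-first connectivity on the induced subnetwork;
  substitution requires the entering node to stay adjacent to the remaining
  set, which preserves connectivity without a second search.
* Missing lipids: a reaction with any unquantified participant is dropped
  from the reaction network before scoring. Sum species with empty
  expansions stay as isolated network nodes and are reported.
* Half-minimum imputation (optional, on by default in the reader) is applied
  per lipid after the measured-fraction filter; ratio-based scores require
  strictly positive abundances and refuse anything else.
* Components smaller than `minSize` are skipped with a warning and
  serialised with explicit empty markers.

# Limitations

Substrate–product changes are computed per reaction, independently;
propagated effects through shared species are not modelled, and the method
returns a set of candidate class reactions, not an individual enzyme. The
bundled registry and reaction table are a reduced curation intended for
method development and testing; serious use should supply a fuller curated
table through the documented TSV dialects.
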