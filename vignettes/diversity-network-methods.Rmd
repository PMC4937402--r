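---
title: "Methods: Hill-number profiles and signed co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hill-number profiles and signed co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillnet)
```

# Scope and model

`hillnet` analyses a features × samples abundance matrix (OTU counts,
metabolite abundances, or per-sample diversity values) along two axes:
the shape of each sample's species-abundance distribution, summarized
as a Hill-number profile, and the pairwise association structure
between features, summarized as signed Pearson correlation networks.
Both halves deliberately use the simplest classical estimators — raw
Pearson on abundances, no compositional transformation, no
multiple-testing correction by default — because the workflow's purpose
is the faithful reproduction of that widely used analysis style,
together with honest tooling (ground-truth simulation, recovery tests)
to probe what it can and cannot detect.

## Hill numbers

For one sample with relative abundances $p_1,\dots,p_S$ (zeros removed,
$\sum_i p_i = 1$), the diversity of order $q \ge 0$ is
$$^qD = \Big(\sum_{i=1}^S p_i^q\Big)^{1/(1-q)}, \qquad
  ^1D = \exp\Big(-\sum_i p_i \ln p_i\Big),$$
the second being the $q \to 1$ limit. All logarithms are natural: the
$\exp/\ln$ pairing is what makes $^1D$ an *effective number of
species*, i.e. the size of an equally-abundant community with the same
entropy. $^0D$ is richness and $^2D$ the reciprocal Simpson
concentration. Orders within $10^{-9}$ of 1 are routed to the limit
form; elsewhere the power form is evaluated directly, which is stable
for the default grid $q = 0,1,2,3,4$.

Numerical conventions: zero-count features are dropped *before*
normalization (they carry no information at $q>0$, and richness counts
only features present); an unnormalized vector is an error rather than
being silently rescaled, so that the caller controls what "relative
abundance" means; profiles are invariant to rescaling counts by any
positive constant, which the tests assert.

## Group comparison

Group mean profiles are arithmetic means per order; two-group
comparisons use the classical two-sided pooled-variance Student t-test
(`stats::t.test(var.equal = TRUE)`), one test per order, requiring at
least two samples per group. `compareGroupsT()` exposes an explicit
`exclude` argument for sensitivity analyses such as dropping the
baseline sample of a longitudinal series; nothing is excluded by
default, because encoding such a choice silently would change reported
means without a visible trace. The bundled reference profiles
(`milkDiversityData()`) demonstrate both conventions.

## Signed correlation networks

For every tested feature pair, $r$ is the Pearson coefficient and the
two-sided p-value comes from $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$
degrees of freedom. An edge is kept iff $p \le \alpha$ (non-strict,
default $\alpha = 0.05$), signed by the sign of $r$. Three
constructions share this core:

* **SIN** — all unordered pairs within one table, typically one OTU
  table per treatment group, each group first filtered by
  `filterLowTotal()` (a feature is kept iff its within-group total
  $\ge$ 5; totals exactly at the threshold are kept). All features
  remain as nodes, connected or not.
* **DMN** — per-sample Hill numbers at each order (nodes `q0`…`q4`)
  cross-correlated against metabolites.
* **MON** — metabolites cross-correlated against OTUs.

In cross-table mode only cross pairs are tested and nodes touching no
edge are dropped, matching the convention that such graphs display
associated features only. Constant features have undefined
correlations and participate in no edge. Fewer than three shared
samples is an error.

Open choices and how they were resolved:

* *Raw vs. relative abundances*: correlations run on raw abundances by
  default with `relative = TRUE` available. Raw counts are the
  classical choice for this workflow; the compositional caveat (total
  count constraints can induce spurious negative correlation) is real,
  and users wanting robustness should treat SparCC-class methods as
  out of scope here.
* *Multiple testing*: off by default — the raw $p \le 0.05$ rule is
  the construction being reproduced — with a Benjamini–Hochberg option
  (`adjust = "BH"`).
* *Sample set for DMN/MON*: the functions take whatever tables they
  are given and use the intersection of sample ids; the caller decides
  whether patient-only or all samples enter, since that choice is a
  study-design question the software should not guess.

## Network summary panel

`summarizeNetwork()` reports unweighted, undirected statistics: node
and edge counts, average degree $2E/N$, density $2E/(N(N-1))$, average
local clustering (degree < 2 contributes 0), diameter and mean
shortest path on the **largest connected component** (the only
finite-valued convention for fragmented graphs), community count and
modularity, signed edge counts and the P/N ratio. The P/N ratio is
$E^+/E^-$, with `Inf` as the distinguished no-negative-links value and
`NaN` for an empty edge set — never a division error.

Community detection is not uniquely defined by any of these analyses;
the default is deterministic greedy modularity maximization
(`cluster_fast_greedy`), with seeded Louvain as an option. Community
counts and modularity values are therefore reproducible under the
package's own conventions but not comparable across tools.

Hubs are the top-3 nodes by degree and MAO ("most abundant OTUs") the
top-3 by total abundance; ties at the cut are all flagged, so the sets
may exceed 3 — dropping tied nodes would make the annotation depend on
input order.

## Motif census and dense modules

`motifCensus()` counts induced connected subgraphs of sizes 3 (path,
triangle) and 4 (path, star, cycle, tadpole, diamond, clique),
ignoring signs. Induced-subgraph semantics are used throughout, and
the tests pin the implementation to a brute-force enumeration oracle
on every random graph up to 12 nodes. The census covers the complete
connected isomorphism classes rather than any tool-specific subset.

`mcodeClusters()` implements molecular-complex detection: each vertex
is weighted by $k \cdot \text{density}$ of the highest $k$-core of its
closed neighborhood; complexes grow greedily from the highest-weighted
unused seed, admitting neighbors whose weight exceeds
$w_{seed}(1-\text{nodeScoreCutoff})$; post-processing discards
complexes without a 2-core and (by default) trims each complex to its
2-core ("haircut"). Parameters default to the published defaults
(degree cutoff 2, node score cutoff 0.2, k-core 2, haircut on, fluff
off). Output is deterministic: seeds are ordered by weight with name
tie-breaks, and clusters are ranked by descending score, then size,
then name.

The reported **cluster score is internal edges divided by member
nodes**. This is an empirical fidelity choice: it exactly reproduces
the strength values published alongside such clusters (e.g. 110 edges
on 16 nodes → 6.875; 22 on 9 → 2.444; 6 on 4 → 1.5), which the
textbook "density × size" definition does not.

## The synthetic-data generator

`generateOtuTable()` draws counts from a log-normal–Poisson model.
Baseline weights follow a *ranked log-normal* species-abundance
distribution whose width is the `dominance` parameter (log-scale
standard deviation): 0 gives a perfectly even community, larger values
concentrate abundance and steepen the Hill profile. Planted pairs
share a standard-normal latent factor with loadings solved in closed
form so the latent-abundance Pearson correlation equals the target
(same-signed loadings for positive pairs, opposite for negative);
total log-noise is `logNoiseSd` (default 0.4), which caps attainable
negative correlations near $|r| \approx 0.85$ — a structural property
of log-normal variables, stated as an error when an infeasible target
is requested. Poisson sampling attenuates realized correlations
slightly, which is why planted pairs occupy the most-abundant ranks.
Poisson rather than multinomial noise is deliberate: the inference
being validated is plain Pearson on abundances, and the generator
matches that model rather than adding compositional closure.

`generateMetaboliteTable()` couples each designated metabolite to the
standardized per-sample $^1D$ with a signed effect size plus Gaussian
noise (population correlation $\pm e/\sqrt{e^2+1}$), shifted positive;
uncoupled metabolites are independent noise.

`simulateMilkStudy()` fixes the study conditions the package's tests
exercise: groups of 8/8/9 samples; 70 OTUs per group at depth 20,000;
dominance 1.6 for the healthy group and 2.4–2.6 for the patient
groups, chosen once so that simulated profiles land near the observed
regime (healthy $^1D \approx 19$–20 of $\approx 60$–70 observed OTUs,
patient $^1D \approx 7$–9) — these values were set from the published
diversity levels, not tuned to test outcomes; group-specific planted
edge sets in which the pre-chemotherapy group carries almost no
negative pairs; and nine diversity-coupled metabolites (4 positive, 5
negative, effect 3, noise 0.5) among 11 noise metabolites. One integer
seed drives every draw, and identical seeds give bit-identical tables.

What the generator does **not** emulate: compositional closure and
sequencing-depth artifacts (so the broad excess of positive
correlations seen in real count data, and hence extreme P/N ratios at
tiny $n$, are not reproduced); taxonomic structure; longitudinal
autocorrelation within the patient series; metabolite–OTU causal
pathways beyond the shared diversity signal. Passing recovery tests
therefore demonstrate correctness of the estimators on data satisfying
their assumptions, not robustness to the compositional biases of real
16S counts.

## Problem sizes in the test suite

The recovery properties run at sizes chosen to keep sampling error
well below the asserted margins while remaining quick: planted-edge
precision/recall uses 40 OTUs × 200 samples over 20 seeds (at
$n = 200$ the null maximum $|r|$ across 780 pairs stays far below the
0.7 reporting threshold); the diversity–metabolite partition uses 60
OTUs × 100 samples; generator calibration checks use 20 seeds each.
The whole suite runs in well under a minute.

## Known limitations

* Pearson on raw counts inherits compositional and outlier
  sensitivity; at $n = 8$–9 samples per group a single sample can
  create or destroy edges. The package reproduces that analysis; it
  does not defend it.
* With $\alpha = 0.05$ and no correction, a $k$-feature table yields
  $\approx 0.05\binom{k}{2}$ false edges; network-level statistics on
  small cohorts should be read accordingly.
* MCODE cluster *membership* depends on expansion order in ways the
  original tool does not fully document; scores and the planted-module
  recovery are stable, but member-for-member agreement with other
  implementations is not guaranteed.
* Beta diversity, rarefaction, partial correlations and time-lagged
  analyses are out of scope.
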