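# hillnet

Integrated diversity–network analysis for small-cohort microbiome and
metabolome studies.

Classical alpha-diversity indices compress a community into one number;
co-occurrence analysis ignores abundance structure entirely. `hillnet`
implements both halves of an integrated workflow and the glue between
them, for datasets of the kind produced by 16S OTU tables plus GC–MS
metabolite panels on a handful of samples per group (e.g. a
longitudinal patient series against a healthy cohort).

## What it computes

**Hill-number diversity profiles.** For a sample with relative
abundances *p₁…p_S*, the diversity of order *q* is

    ᵠD = (Σᵢ pᵢᵠ)^(1/(1−q)),     ¹D = exp(−Σᵢ pᵢ ln pᵢ)  (the q→1 limit)

in units of effective species: ⁰D is richness, ¹D the exponential of
Shannon entropy, ²D the reciprocal Simpson index. The profile over
*q* = 0…4 summarizes the whole species-abundance distribution;
profiles are compared between groups with pooled-variance t-tests.

**Signed correlation networks.** Three network types are built from
pairwise Pearson correlations retained at *p* ≤ 0.05: species
interaction networks (SIN; OTU × OTU within one group, after removing
OTUs with group totals < 5), diversity–metabolite networks (DMN; Hill
orders q0–q4 × metabolites), and metabolite–OTU networks (MON). Each
edge carries *r*, *p*, and a sign, and each network is summarized by
the usual panel (degree, density, clustering, path lengths,
communities, modularity) plus the **P/N ratio** — positive over
negative edge counts, a proposed contrast between healthy and
perturbed communities.

**Module and motif structure.** A census of connected 3- and 4-node
motifs, and MCODE-style dense-module detection (k-core–weighted
seeded expansion) with each cluster scored as internal edges per node,
plus per-cluster inventories of negative links.

**Synthetic data.** A seeded log-normal–Poisson generator plants
pairwise correlations of chosen sign and magnitude and
diversity-coupled metabolites, returning the ground truth so that the
entire pipeline is testable by recovery.

## Worked example

The package ships the per-sample Hill numbers of a published milk
microbiome study (healthy donors vs. one donor sampled before and
after chemotherapy):

```r
library(hillnet)
md <- milkDiversityData()
round(groupMeanProfile(md$profiles, md$groups), 3)
#>             q0     q1     q2    q3    q4
#> healthy 46.000 19.238 12.405 9.997 8.867
#> post    54.750 10.718  6.643 5.484 4.942
#> pre     55.125  8.855  5.173 4.216 3.795
compareGroupsT(md$profiles, md$groups, "healthy", "pre")
#>    q     meanA     meanB         t            p
#> 1 q0 46.000000 55.125000 -5.531644 5.754230e-05
#> 2 q1 19.237778  8.855500  5.105947 1.290656e-04
#> ...
```

Healthy samples hold ~19 effective common species (q = 1) against ~9
before chemotherapy — a significant diversity deficit at every order
(p < 0.001) — while richness (q = 0) runs the other way.

A full synthetic run, from simulation through networks, modules and
group tests:

```r
sim <- simulateMilkStudy(seed = 5, outDir = "sim")
res <- runPipeline(pipelineConfig(otu = "sim/otu.tsv",
                                  groups = "sim/groups.tsv",
                                  metabolites = "sim/metabolites.tsv",
                                  outDir = "out"))
res$summaries[, c("group", "n_nodes", "n_edges",
                  "n_positive", "n_negative", "pn_ratio")]
#>           group n_nodes n_edges n_positive n_negative pn_ratio
#> healthy healthy      70     128         72         56 1.285714
#> post       post      64      95         59         36 1.638889
#> pre         pre      64     128         88         40 2.200000
```

The pre-chemotherapy group — simulated with almost no planted negative
pairs — shows the highest P/N ratio, the qualitative signature the
workflow is designed to expose. `out/` then contains per-group GraphML
networks, the summary panel, cluster and motif tables, diversity
t-tests, the DMN/MON graphs and a JSON manifest that reproduces the
run.

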