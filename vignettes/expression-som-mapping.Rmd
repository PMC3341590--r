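---
title: "Mapping multi-experiment expression profiles with exprSOM"
author: "exprSOM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping multi-experiment expression profiles with exprSOM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprSOM)
```

## The problem

Public expression compendia for a single organism typically combine
many independent experiments — different platforms, designs and
laboratories — into one gene-by-condition table. Two obstacles stand
between such a table and a usable global view of co-expression. First,
"reference-less" experiments (single-channel intensities, global
reference designs) have no common zero, so values cannot be compared
across experiments without normalization. Second, the table is large,
sparse and heterogeneous: thousands of genes, tens of conditions,
missing cells, and experiments whose dynamic ranges differ by an order
of magnitude.

exprSOM addresses both. Profiles are median-shift normalized within
experiment blocks, then clustered onto a two-dimensional self-organizing
map (SOM) whose similarity measure is the Pearson correlation computed
over jointly observed components only. The trained map places genes with
similar multi-experiment profiles on the same or nearby nodes, which
makes three downstream analyses natural: per-node over-representation of
functional annotations, an empirical test for the spatial non-randomness
of an arbitrary gene set, and a reproducibility assessment of the layout
across independently seeded trainings.

## Median-shift normalization

For each gene and each experiment in the plan, the median of the gene's
non-missing values across that experiment's conditions is subtracted
from each of those values:

```{r}
v <- matrix(c(11, 4, 6), 1, dimnames = list("g1", c("c1", "c2", "c3")))
em <- ExprMatrix(v, c(c1 = "e1", c2 = "e1", c3 = "e1"))
exprValues(medianShift(em))
```

Conventions that the definition leaves open are fixed as follows and
tested: the median of an even number of values is the midpoint of the
two central order statistics; the median is taken over non-missing
values only, so a single observed value normalizes to 0; missing entries
stay missing; a gene with no observed value in an experiment is left
untouched there. The operation is idempotent and invariant to per-block
constant shifts. Which experiments need shifting depends on their
measurement technology, so the set of shifted experiments is explicit
user configuration (default: all). Range normalization is deliberately
not offered: rescaling every experiment to a common range would destroy
the biologically meaningful differences in response magnitude between
experiments.

## The self-organizing map

The map is a `width` x `height` grid of node vectors with one component
per condition. Training follows the classical on-line algorithm:

1. Initialize every node-vector component for condition c uniformly
   within the [min, max] of the observed values of c.
2. For presentation t = 0 ... T-1 (T = `presentationsPerGene` x number
   of genes): draw a gene uniformly with replacement; find the best
   matching unit (BMU), the node with the highest similarity; update the
   BMU and every node within the current radius towards the input by the
   current learning rate, skipping input components that are missing.
3. The learning rate and radius decay linearly to zero:
   alpha(t) = lr0 (1 - t/T), r(t) = radius0 (1 - t/T).
4. After training, every gene is assigned once more to its closest node.

Defaults (`SOMConfig()`): 25 x 20 grid (500 nodes), lr0 = 0.1,
radius0 = 10, 20 presentations per gene, Pearson similarity. The
defaults suit a compendium on the order of 10^4 genes, where they yield
about 20 genes per node on average; the validation runs in this package
use a 15 x 10 grid for 2000-gene inputs to keep roughly the same
occupancy.

Numerical and design choices that the classical algorithm leaves open,
all fixed and documented here as configuration rather than claimed as
canonical:

* **Similarity with missing data.** Pearson correlation over jointly
  observed components; pairs with an overlap below `minOverlap`
  (default 3) or with zero variance over the overlap are *incomparable*
  and receive a `-Inf` score that can never win a BMU contest. A gene
  incomparable to every node is a hard error naming the gene. The
  `euclidean` alternative negates the distance over the overlap and
  divides by the square root of the overlap size, so profiles with
  different missingness remain comparable; the zero-variance rule does
  not apply to it.
* **Neighbourhood.** City-block grid distance with a flat ("bubble")
  update at full learning rate, consistent with the city-block metric
  used by the spatial statistics; the comparison `distance <= r(t)` uses
  the real-valued radius without rounding. A Gaussian kernel and
  Chebyshev grid distance are available as options.
* **Tie-break.** Equal similarities resolve to the smallest (y, x)
  coordinate, making training and assignment fully deterministic given
  the seed.
* **Edges.** The grid has hard boundaries (no toroidal wrap-around), so
  edge and corner nodes have smaller neighbourhoods.
* **Missing input components** leave the corresponding node components
  unchanged during that presentation; nodes are never skipped wholesale.

Node coordinates are 0-based, x for the column (0 .. width-1), y for the
row (0 .. height-1).

## Per-node over-representation analysis

Each occupied node is treated as a gene cluster and tested for
over-representation of annotation terms with the one-sided Fisher /
hypergeometric upper tail, under the null that genes with a term are
randomly distributed between the node and the rest of the map. The
universe N is all mapped genes, including unannotated ones. Three
filters shape the result, mirroring standard practice for cluster-wise
GO scans:

* Terms annotating fewer than ten (K <= 9) or more than a quarter
  (K > N/4) of the mapped genes are excluded before testing.
* All performed (node, term) tests are corrected jointly with the
  Benjamini–Hochberg step-up procedure (`bhFDR()` exposes the family
  size `m` explicitly).
* A (node, term) pair is only *reported* when its FDR passes the
  threshold **and** at least four genes in the node carry the term.

Parent/child term overlap is deliberately not corrected for. Whether
annotations should first be closed under `is_a`/`part_of` ancestors is
left as an explicit optional step (`propagateAnnotations()`), not a
silent default. When counting "distinct" enriched terms across
thresholds (`countEnrichedTerms()`), terms whose annotated mapped-gene
sets are identical collapse to one, since the test cannot distinguish
them; this identical-set rule is the package's definition of
non-redundancy.

## Spatial non-randomness of a gene set

Over-representation per node misses gene sets that concentrate in a map
*region* without filling any single node. The empirical test takes the
set's observed statistic d — the mean city-block distance of each member
to its closest within-set neighbour — and compares it with d' from
`nSamples` same-size sets sampled uniformly without replacement from the
mapped genes. The estimated p-value is the fraction of samples with
d' strictly below d; ties count as "not smaller", so p = 0 is
reportable, and the add-one estimate (count + 1)/(nSamples + 1) is
carried alongside as a clearly labelled conservative extension. With
multiple sets, the Bonferroni correction multiplies p by the number of
tests; `scaleSamplesByTests` optionally raises the sample count by the
same factor so the attainable resolution matches the corrected scale.

## Reproducibility across re-seeded maps

Because training is stochastic, the assignment is only meaningful to the
extent that it is reproducible. `coclusterReproducibility()` samples
co-clustered pairs from a reference map — uniformly over the multiset of
all within-node pairs, which weights nodes by their pair count — and
checks each pair on a randomly chosen re-seeded map: "same" means the
identical node, "near" means within `nearRadius` grid units (city-block,
default 5). The occupancy-based chance level for "same",
sum_j c_j (c_j - 1) / (G (G - 1)), gives the natural null reference;
pairs are drawn with replacement.

## The synthetic-data generator

`simulateExpression()` emulates the structure of a curated
multi-publication compendium without attempting to reproduce real
measured values: several experiment blocks of a few conditions each,
planted co-expression clusters (archetype profiles plus gene-level
noise), per-cell missingness, and per-experiment dynamic-range
multipliers that make some experiments dominate the correlation
structure the way wide-range experiments do in real compendia. The
defaults — 2000 genes, 4 blocks totalling 20 conditions, 10 clusters,
noise sd at 0.3 of the cluster sd, 5% missing cells, multipliers
(2, 1, 0.5, 1.5) — are the package's standing validation conditions:
large enough to exercise every stage, small enough that the full test
suite trains a dozen maps in minutes. All randomness derives from one
seed through fixed substream seeds, so adding draws to one stage cannot
shift another stage's stream. `simulateAnnotations()` plants one term
per cluster (90% of the cluster, 5% background by default), giving an
end-to-end ground truth for the enrichment stage.

What the generator does *not* model — and what green tests therefore do
not demonstrate about real data: platform- and batch-specific biases,
correlated (non-independent) missingness, heavy-tailed noise, cluster
overlap and genes belonging to no cluster, and annotation ontologies
with realistic depth. Results on real compendia additionally depend on
upstream preprocessing quality, which is out of scope here.

## Validation scales and expected behaviour

The test suite fixes these problem sizes, chosen to probe each property
at the smallest scale where it is meaningful:

* End-to-end recovery: the default 2000-gene / 10-cluster conditions on
  a 15 x 10 map recover at least 8 of the 10 planted terms at
  FDR <= 0.01 for each of three seeds, and intra-cluster grid distances
  stay below inter-cluster distances in five of five seeded runs.
* Calibration: on a trained map, 200 random 30-gene sets yield
  p < 0.05 in 2–9% of cases (the binomial tolerance at that volume),
  and random annotations produce no reported term at FDR <= 1e-6;
  a 30-gene set confined to single nodes reaches p = 0 at 1000 samples.
* Exactness: the Fisher upper tail agrees with a brute-force
  tail sum to relative error below 1e-10 over every valid contingency
  with N <= 60, and the BH adjustment reproduces hand-derived step-up
  values.
* Smaller fixtures (200–500 genes, 4–10 clusters, 6 x 5 to 10 x 8
  grids) cover co-location of well-separated profiles, the
  above-chance re-mapping of co-clustered pairs, and determinism
  bit-for-bit.

## Known limitations

The map size, like any SOM grid choice, is somewhat arbitrary; no
automatic size selection is attempted. Training is on-line and
single-threaded; very large compendia will be slow in pure R. The
enrichment stage implements only the over-representation mode, not
score-resampling alternatives. The spatial test's null is sampling-based
by design; no analytic approximation is provided. Region outlines are
node sets plus 4-connected components; figure-quality drawing is out of
scope.

## A worked run

```{r, eval = FALSE}
sim <- simulateExpression(seed = 7)
normed <- medianShift(sim$matrix)
map <- trainSOM(normed, SOMConfig(width = 15, height = 10, seed = 7))
ann <- simulateAnnotations(sim$truth, seed = 7)
res <- runEnrichment(map, ann, fdrThreshold = 0.01)
countEnrichedTerms(res, c(0.01, 1e-6))
```

See the README for the printed output of this run and
`runPipeline()` for the file-based orchestration of the same stages.
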