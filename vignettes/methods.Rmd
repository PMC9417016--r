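---
title: "From individual cognitive maps to a social representation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From individual cognitive maps to a social representation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repmap)
```

## The data model

An *individual cognitive map* (ICM) is one respondent's signed directed
graph over the components of a social-ecological system: an edge
`(u, v, +1)` means the respondent believes `u` influences `v` positively,
`(u, v, −1)` negatively. Maps carry at most one signed edge per ordered
pair, no self-loops, and may contain isolated nodes — citing a component
without linking it is still a datum, and all counting rules treat isolated
nodes as cited components with zero links.

Maps exist at three condensation levels. At the `raw` level nodes are
verbatim elicited labels; a *condensation catalog* maps each raw label to
a `component`, each component to a `type`, and each type to one of six
fixed categories (biophysical, social, ecosystem service, ecosystem
disservice, positive human action, negative human action). Matching is
performed on normalized labels (trimmed, internal whitespace collapsed,
case-folded) because transcripts vary typographically, while original
spellings are preserved for audit. The catalog invariants — one type per
component, one category per type, raw labels unique after normalization —
are enforced at load time and violations are named errors, never silent
repairs.

## Condensation and conflict handling

Condensing a map re-tallies all finer-level edges between the preimages of
each ordered pair of condensed nodes. The merged sign is the majority
sign, `sign(pos − neg)`. Two non-obvious cases are handled explicitly:

* **Exact ties** (`pos = neg > 0`) become *conflict edges* with sign 0.
  They are excluded from the signed edge set and from link counts but kept
  on the map and in reports: a silent sign choice would bias every
  downstream metric, and elicited maps carry a single ±1 per link, so a
  tie is a genuine ambiguity.
* **Would-be self-loops** — edges whose endpoints merge into one node —
  are dropped and counted. They are artifacts of condensation, not
  respondent intent, so they are not errors.

Condensation at a map's own level is the identity, making the operation
idempotent; node counts never increase and
`edges_after + conflicts ≤ edges_before`. These properties are tested
against a brute-force oracle that groups preimages and re-tallies with
explicit loops.

## The social cognitive map

Aggregation is matrix addition: the SCM's weight matrix is the entrywise
sum of the individual signed adjacency matrices padded to the union node
set. We keep, per ordered pair, the positive and negative tallies
separately (`weight_sum = pos − neg`, `occurrence = pos + neg`), because
collapsing to the net sign would erase *ambivalent links* — pairs judged
positive by some respondents and negative by others — which are themselves
a finding about disagreement. Aggregation is associative and
permutation-invariant, and conserves links:
`Σ_maps L(map) = Σ_pairs occurrence(pair)`.

Display filters use **strict** inequalities, matching the conventional
captions "cited by >10% of the respondents" (nodes), ">10 respondents"
(SCM links) and ">2 respondents" (focal-map links): a node at exactly 10%
citation is excluded. Focal subgraphs are 1-hop and direction-agnostic —
the focal components plus every component linked to them through a
surviving record — because the question they answer is "what do
respondents connect to this challenge", not "what is reachable from it".

## The centrality–frequency method

Each component receives two indicators:

* **frequency** `f = (maps citing it) / R` — the level of agreement among
  respondents that the component belongs to the system at all;
* **median centrality rank** — within each citing map, components are
  ranked by degree centrality (the sum of absolute weights of incident
  in- and out-edges, the standard importance proxy in fuzzy-cognitive-map
  practice), ties receiving average ranks; the component's indicator is
  the median of its ranks over exactly the maps that cite it.

Crossing the two yields the four zones of the structural approach to
social representations: *core* (high f, central), *first periphery*
(high f, peripheral), *contrasting elements* (low f, central — components
known to few respondents but central to those who know them), *second
periphery* (low f, peripheral).

Design choices, where the method is genuinely open:

* **Cuts default to medians** of the observed frequency and median-rank
  distributions. A median split is the standard practice of the
  structural approach and makes no distributional assumption; the
  resolved cut values are stored in the output so any classification can
  be audited or redone with fixed cuts. No published percentage (such as
  a particular frequency threshold) is hard-coded.
* **Ties at a cut go to the high/central side** (`f ≥ cut` is "high",
  `rank ≤ cut` is "central"), so boundary components err toward the core
  rather than dropping out of it.
* **Raw ranks are the default**; `relative` mode (rank divided by map
  size) is exposed because map sizes can vary severalfold and a rank of
  10 means something different in a 20-node and a 97-node map. Both modes
  are reported with the ranking mode stored in the result.
* **Zoning is done at the component level** by default (classification is
  about components; type-level display is a separate summary), and
  components cited once are classified like any other — their median rank
  is that single rank — with an optional minimum-citation filter.

The full chain (frequency → ranks → zones) is verified against an
independent brute-force implementation on 1000 random collections, and
zone *recovery* is scored on synthetic data with planted zones.

## Respondent ordination and clustering

Nine active variables describe each map: component count N, link count L,
density `D = L/(N(N−1))` (directed, no self-loops; the denominator
convention is fixed and documented because mean densities alone cannot
discriminate it from L/N²), and the six category proportions (which sum
to 1). Because these mix counts and proportions on different scales, the
PCA is a correlation PCA — every variable centered and scaled to unit
variance; total inertia equals 9. The respondent's stakeholder group is a
*supplementary* variable: its categories are projected as centroids of
member scores and never influence the axes. Axis signs are fixed so each
axis's dominant variable loads positively, which makes outputs
reproducible across numerical libraries. A constant column is an error
naming the column (a metric that cannot vary carries no information and
usually signals an upstream bug; a category absent from every map should
reach the PCA as structural zeros only if some maps differ).

Clustering is Ward linkage (`ward.D2`) on Euclidean distances in the
retained-score space; the default retention is the smallest axis set
reaching 80% cumulative variance. The automatic cluster count maximizes
the ratio of successive between-inertia gains over k ∈ [2, min(10, R−1)]:
the chosen cut is the last one that buys substantially more between-group
inertia than the next. K-means consolidation from the hierarchical
centroids is available but off by default, so results are reproducible
from the linkage alone. Cluster comparison reports per-metric means and
SDs (n−1) and a two-sided pooled-variance Student t by default (Welch as
an option); no multiple-testing correction is applied by default, with a
Holm option, since the comparison table is descriptive.

## The synthetic generator

The generator emulates the study conditions under which the pipeline is
meant to operate: 32 respondents; a universe of 162 components in 32
types and six categories; per-map sizes bounded to [20, 97]; two
equally-sized respondent clusters ("ecocentric" and "social-ecological")
with map-size means/SDs of 29.1 ± 7.6 and 45.8 ± 10.1, links-per-node
rates implying ≈42 and ≈81 links per map, and category mixes differing
most in the social, biophysical and negative-human-action shares
(0.08 vs 0.05 for the latter). Stakeholder-group composition per cluster
follows the corresponding survey mix. Within these conditions:

* **Map sizes** are drawn from truncated normals whose *realized* mean and
  SD equal the configured values: the underlying normal parameters are
  recovered by moment matching, since truncation at 20 would otherwise
  inflate the small cluster's mean and shrink the contrast between
  clusters. Sizes are realized exactly (weighted sampling without
  replacement of that many components), so the configured SDs are not
  inflated by additional inclusion noise.
* **Zone structure** is planted by assigning each component a citation
  probability drawn from its zone's interval (defaults: core 0.65–0.90,
  first periphery 0.55–0.85, contrasting 0.10–0.30, second periphery
  0.04–0.22; zone counts 31/24/20/87). Separation is parameterized so
  recovery tests can sweep difficulty. Core and contrasting components
  receive a degree boost (default ×3) when links are drawn, planting the
  centrality signal the zoning method must detect.
* **Links** are sampled among a map's nodes with weight
  `boost(u) · boost(v) · salience(u, v)`, where the per-pair salience is
  lognormal, drawn once at the universe level and shared by all
  respondents — interviewees tend to cite the same well-known causal
  relations, which is what makes occurrence thresholds (">10
  respondents") meaningful. Link counts follow the cluster's
  links-per-node rate with lognormal spread calibrated to the configured
  link SDs net of the size-induced component (log-scale SDs 0.20 / 0.39).
* **Signs** come from a fixed per-ordered-pair ground truth (+1 with
  probability 0.7) flipped with probability 0.1 per emitted edge — the
  simplest mechanism that reproduces ambivalent links while keeping a
  recoverable truth.

What the generator does *not* emulate: interview language (labels are
synthetic identifiers), respondent-specific elicitation depth beyond map
size, correlation between a respondent's category mix and which specific
components they choose within a category, and any spatial or temporal
structure. Passing recovery tests therefore shows that the pipeline
detects planted structure of the kind and strength described above — not
that it would extract the same structure from any real interview corpus.

## Numerical choices and degenerate inputs

Randomness is always drawn under a caller-supplied seed through a local
RNG scope that restores the caller's RNG state; the full pipeline is a
pure function of (inputs, configuration, seed) and repeated runs are
byte-identical. Density of a map with fewer than two nodes is defined as
0. Average ranks are used for all centrality ties. The median of an even
number of ranks is the midpoint average. Zero-variance metrics in the
cluster comparison yield t = 0, p = 1 when the group means agree (and
±Inf, p = 0 otherwise) instead of erroring, since an all-zero category
row is a legitimate study outcome. Empty collections, mixed condensation
levels, unresolvable labels, duplicate respondents, conflicting duplicate
edges and absent focal nodes are all named errors raised by the stage
that detects them.

## Problem sizes used in the checks

The test suite verifies oracle equivalence on 1000 random collections
(zoning chain) and 500 collections (aggregation) of up to 8 maps × 12
components; cluster recovery on 20 study-scale collections (ARI vs
planted clusters) plus 100 collections for the component-count t test;
zone recovery on 20 collections under strong separation (core citation
probability 0.80–0.95 and ×3 degree boost vs periphery 0.05–0.30); and
calibration of the size distribution on 1024 generated maps. These sizes
were chosen to exercise every code path at study scale while keeping the
default test run fast.

## Known limitations

Under exactly the configured two-cluster contrast (n = 16 + 16, component
means 29.1 vs 45.8, SDs 7.6/10.1), the theoretical power of a two-sided
pooled t test at α = 0.001 on the component count is 0.93 — so across
many seeds, roughly one run in fourteen will not reach p < 0.001 on that
metric even though the clusters are real and recovered. The adjusted Rand
index of automatic clustering against the planted labels averages ≈0.89,
not 1: with clusters this close, a few respondents genuinely sit between
profiles. Both numbers are properties of the configured conditions, not
of the implementation; stronger contrasts yield perfect recovery, which
the tests also verify on separated instances.
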