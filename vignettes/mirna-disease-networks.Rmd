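---
title: "Matching-based disease prioritization and motif analysis on miRNA-disease networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching-based disease prioritization and motif analysis on miRNA-disease networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdnet)
```

## The model

Curated miRNA-disease association databases can be read as a weighted
bipartite graph: one partition holds miRNAs, the other diseases, and an
edge between miRNA $i$ and disease $j$ carries an integer weight
$W_{ij} \ge 1$ — the number of distinct publications reporting that the
miRNA up- or down-regulates the disease. A publication reporting both
directions counts once; when per-citation PubMed ids are available the
weight is always the distinct-id count, and it wins over an inconsistent
weight column. Identifiers are matched case-insensitively after trimming,
and stored in their first-seen form. `md_graph()` builds and validates
this structure; `read_edge_csv()`/`write_edge_csv()` move it to and from a
plain CSV with `;`-separated multi-valued citation cells.

Given a query set of miRNAs, the package answers: *which diseases does
this set, acting together, most plausibly impact?* Two routes are
provided.

### Route 1: maximum-weight matching plus merge rule

The optimization selects vertex-disjoint associations maximizing total
support:

$$\max \sum_{i,j} W_{ij} X_{ij}
  \quad\text{s.t.}\quad \sum_j X_{ij} \le 1 \;\forall i,\qquad
  \sum_i X_{ij} \le 1 \;\forall j,\qquad X_{ij} \in \{0,1\}.$$

One constraint per miRNA and one per disease: no vertex is used twice.
Because the assignment polytope is integral on bipartite graphs, the
combinatorial solution solves this integer program exactly. `mwm_solve()`
implements the $O(n^3)$ Hungarian algorithm on the zero-padded square
profit matrix; weights are handled in exact integer arithmetic.
`export_gmpl()` emits the same program as GNU MathProg text for use with
external LP tooling.

Vertex-disjointness has a known artifact: on the bundled five-edge
example (`worked_example()`: m1-d1 = 20, m1-d2 = 30, m2-d3 = 2,
m3-d3 = 16, m3-d4 = 10) the optimum (objective 46) picks (m1, d2) and
(m3, d3), discarding m1-d1 with weight 20 simply because m1 is better
used on d2. The repair is the *cumulative impact* ranking
(`cumulative_impact()`): each disease scores the sum of weights from all
queried miRNAs. The merge rule (`merge_ranking()`) takes $t$, the least
cumulative impact among matching-selected diseases, and adds every
disease with impact strictly greater than $t$, emitting the final list in
ranking order. "Strictly greater" is deliberate: ties with the threshold
disease do not enter, which keeps the rule stable under re-application
(merging the final set again adds nothing — the suite tests this
idempotence). `prioritize()` chains the steps on the subnetwork induced
by the query and its adjacent diseases:

```{r}
prioritize(worked_example(), c("m1", "m2", "m3"))
```

### Route 2: motif participation

The structural route counts connected 3- and 4-node induced subgraphs.
On a bipartite network exactly four classes exist: the 3-path (one miRNA
regulating two diseases, or two miRNAs one disease — undirected, one
class), the 4-path, the 3-star and the square (two miRNAs sharing two
diseases). `motif_census()` enumerates occurrences ESU-style, exactly
once each; `motif_prioritize()` ranks a query's adjacent diseases by
total participation across a configurable class set. The class set is a
parameter because square-only and pooled counts both have sensible
readings; the default pools all four.

Significance (`motif_significance()`) compares real counts against a
degree-preserving null: `randomize_edges()` performs
`round(swap_factor * E)` attempted double edge swaps — rewiring (a,b),
(c,d) to (a,d), (c,b) only when both rewired edges are absent — which
preserves every node degree, bipartiteness and simplicity exactly.
Reported per class: ensemble mean and SD, $z = (N_{real} - \bar N)/s$,
the empirical $p$ (fraction of null networks with count $\ge$ real), and
*uniqueness*, the size of a greedy edge-disjoint packing of the real
occurrences taken in sorted order (the packing order is fixed because the
greedy optimum is not unique). A significance flag applies the
conventional census-tool thresholds $z \ge 2$, $p \le 0.01$,
uniqueness $\ge 4$; all three are arguments, since they are conventions
rather than constants of nature.

One structural fact worth knowing when reading the output: the 3-path and
3-star counts are functions of the degree sequence alone
($\sum_v \binom{k_v}{2}$ and $\sum_v \binom{k_v}{3}$), so under a
degree-preserving null their ensemble SD is 0 and their z-score is
undefined (flagged `NA`). Only the 4-path and the square can be enriched
or depleted relative to this null. Degenerate ensembles (e.g. $K_{2,2}$,
which admits no legal swap) report SD 0, `NA` z and $p = 1$ for every
class rather than a spurious signal.

### Projection and exploration

`project_diseases()` builds the disease-disease one-mode projection: two
diseases are linked when at least one miRNA regulates both, with the
shared-miRNA count as edge weight (count-1 edges reproduce the unweighted
projection exactly). Isolated diseases are retained so node counts stay
comparable with the source network. The census runs on projections too,
where triangles become possible and are reported as their own class.
`shortest_path()` returns minimum-hop, lexicographically smallest paths
for "how far apart are these two diseases" exploration, and
`degree_summary()`/`graph_density()` summarize topology. Density is the
standard simple-graph $2E/(N(N-1))$ over all nodes; note that densities
reported in the literature for similar networks occasionally differ in
the third decimal from this formula, depending on rounding and on which
node set enters the denominator.

## The synthetic generator

Real association networks are long-tailed: a few hub miRNAs regulate
many diseases. `scale_free_bipartite()` emulates this with bipartite
preferential attachment: starting from a single m1-d1 edge, nodes join
the smaller partition one at a time and attach to
`edges_per_new_node` opposite-partition nodes with probability
proportional to degree + 1. The +1 keeps early low-degree nodes
reachable; pure degree-proportional attachment stalls on the two-node
seed. With balanced partitions of size $n$ and $m$ attachments the edge
count is exactly $m(2n-2)$. Weights are geometric on $\{1, 2, \dots\}$
with success probability 0.4 (mean 2.5) — small positive counts with a
long tail, the shape of supporting-publication counts; the parameter is
exposed. `er_bipartite()` provides Erdős–Rényi-style null fixtures for
oracle tests.

What the generator does *not* emulate: the correlation between a pair's
weight and its endpoints' degrees, partition-size asymmetry of real
databases, and disease co-annotation structure. Passing tests on
synthetic networks therefore validate the algorithms' correctness and
scaling behavior, not biological conclusions about any particular
database.

## Numerical and design choices

* **Determinism.** Every operation with tied optima has a documented
  tie-break, always lexicographic on byte-order-sorted identifiers:
  matchings (smallest sorted pair list, enforced by greedy forced-edge
  re-solves after the Hungarian pass), rankings (disease id on equal
  impact), shortest paths (smallest node sequence), census occurrence
  order, and the uniqueness packing. All randomized procedures take a
  seed and are bit-reproducible from it.
* **Oracles.** The solver is cross-checked against an independent
  branch-and-bound enumeration of all matchings (`mwm_brute_force()`,
  guarded by `max_edges` — default 20, raised explicitly in tests); the
  census against an all-subsets connectivity-and-classify sweep; the
  projection against pairwise common-neighbor counting.
* **Power-law fit.** The exponent is a least-squares slope on
  $\log_{10} P(k)$ vs $\log_{10} k$ — a descriptive diagnostic of
  long-tailedness, not an MLE; it needs at least three distinct degrees.
* **Degenerate inputs.** Empty graphs match with objective 0; empty
  matching sets merge to an empty final list with an explanatory trace;
  queries of entirely unknown miRNAs error, partially unknown ones warn
  and continue; density is refused below two nodes.
* **Problem sizes in the shipped checks.** The test suite and the
  acceptance script validate on 200 random instances up to 8×8 for the
  solver, 50 networks up to 12 nodes for the census, 100 projections,
  100 generator seeds at 250+250 nodes, and a 50-network null ensemble on
  an 80-node synthetic graph — sizes chosen so each oracle comparison is
  exhaustive while the whole suite stays interactive.

## Limitations

The package analyses *known* associations; it does not predict new
miRNA-disease links, and it assigns no probabilistic confidence to
ranks — the scores are publication counts and participation counts.
Motifs are undirected and capped at four nodes. The merge rule's output
depends on the query's induced subnetwork only: associations outside the
queried miRNAs' sphere of influence never appear, by design.
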