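---
title: "Quantifying causal loop diagrams as directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying causal loop diagrams as directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldnet)
```

## The problem

Group model building workshops produce *causal loop diagrams* (CLDs):
shared mental models of a complex problem, drawn as variables connected by
directed causal arrows, optionally signed with a polarity. Community CLDs
for problems such as childhood obesity routinely contain a hundred or more
variables and a couple of hundred links — far beyond what can be reasoned
about by eye. Yet decisions about where to intervene (which variables are
*leverage points*) are usually made from exactly such diagrams.

cldnet treats a CLD as what it formally is: a directed, unweighted, simple
graph with adjacency entries $x_{ij} \in \{0, 1\}$. Every quantity the
package computes is a standard network statistic, chosen for its
interpretation on a systems map:

* **Density** $E / (N(N-1))$ — how much of the possible causal structure
  the group articulated. Sparse maps mean change must be seeded in several
  places.
* **In-/out-degree** — how many causes act on a variable, and how many
  variables it acts on. The right tails are the hubs.
* **Betweenness centrality** $C_B(v) = \sum_{s \ne v \ne t}
  \sigma_{st}(v) / \sigma_{st}$ — the mediators through which causal
  influence between distant parts of the map must travel.
* **Average directed path length** and **diameter** — how quickly change
  can propagate, and the longest minimum causal chain anyone should even
  consider interpreting.
* **Modularity** $Q$ of a detected partition — whether the map organises
  into thematic clusters, which makes the high-betweenness bridges between
  them doubly important.
* **Feedback loops** — directed cycles, the defining objects of system
  dynamics.

## Reading and building a CLD

The package consumes the two-file dialect in which CLDs are typically
shared: a variable key (`id,name`) and an edge list (`source,target`,
optionally a polarity column). Both readers validate aggressively and each
failure mode has its own condition class, so a malformed file can never
silently truncate an analysis:

```{r io}
key <- tempfile(fileext = ".csv")
edges <- tempfile(fileext = ".csv")
writeLines(c("id,name",
             "1,Junk food consumption",
             "2,Energy intake",
             "3,Childhood obesity",
             "4,Food advertising",
             "5,School food policy"), key)
writeLines(c("source,target,sign",
             "1,2,+", "2,3,+", "4,1,+", "5,1,-", "3,1,+"), edges)

g <- build_graph(read_variable_key(key),
                 read_edge_list(edges, polarity_col = "sign"))
g
```

Design rules worth knowing:

* The node universe is the *union* of the key and the edge endpoints, with
  the key authoritative for names. Isolates — variables the group named but
  never wired — are retained: they are part of the mapped system and count
  toward $N$ in the density denominator.
* Self-loops are rejected (a variable "causing itself" has no meaning at
  this grain), and duplicate directed links collapse to one, because the
  network is unweighted.
* Polarity is parsed and stored but used by no metric. Signed analysis
  (reinforcing vs balancing loops, signed centrality) is a different method
  with different semantics, deliberately out of scope here.

## Global structure and centrality

```{r metrics}
edge_density(g)
average_path_length(g)
diameter(g)
centrality_table(g)
find_feedback_loops(g, max_length = 3)
```

Two conventions matter and are fixed throughout the package:

* **Reachable-ordered-pairs average path length.** The mean is taken over
  ordered pairs $(i, j)$, $i \ne j$, that are connected by a directed
  path; unreachable pairs are excluded from numerator and denominator.
  Directed systems maps with isolates have many unreachable pairs, and
  this is the only convention under which a finite, interpretable average
  coexists with them. Unreachability is always the explicit sentinel `NA`,
  never a large stand-in number that could leak into a mean.
* **Unnormalized, directed, endpoint-excluding betweenness.** On a map of
  $N \approx 114$ variables this yields scores in the hundreds, which is
  the scale practitioners of community systems mapping will recognise from
  published analyses. `normalized = TRUE` divides by $(N-1)(N-2)$ when a
  dimensionless score is wanted.

Determinism is treated as a feature of scientific reporting: diameter ties
break toward the smallest `(source, target)` pair, shortest-path ties
toward the lexicographically smallest ID sequence, ranking ties toward the
smaller ID with dense ranks, and feedback loops are canonically rotated to
start at their smallest ID. Re-running a report can never reshuffle it.

Loop enumeration is exponential in the length bound, so `max_length`
defaults to 3 and is capped at 8 unless the cap is raised explicitly.
This is consistent with systems-mapping practice, which discourages
interpreting long causal chains because interference accumulates along
them.

## Community detection

`louvain()` is a multilevel greedy modularity optimiser: repeated
local-move sweeps followed by aggregation, restarted `restarts` times with
seeded node orders, keeping the best partition. Numerical choices:

* The default scoring projects the CLD onto a simple undirected graph
  (symmetrize, drop duplicate arcs) — the same behaviour general-purpose
  network software applies to directed graphs by default, and therefore
  the score comparable with published CLD modularity values. The directed
  variant ($Q = \sum_c [e_c/m - K^{out}_c K^{in}_c / m^2]$) is provided
  for completeness.
* Resolution is fixed at 1; moves require a strict gain ($> 10^{-12}$) so
  sweeps terminate; gain ties go to the lower community label.
* The returned `modularity` is always recomputed from the final assignment
  with `modularity_score()`, so the two can never disagree.
* `q_restarts` exposes the spread across restarts — a partition whose Q
  varies wildly across restarts should be trusted less than a stable one.

```{r louvain}
cl <- function(nodes) subset(expand.grid(source = nodes, target = nodes),
                             source != target)
two_cliques <- build_graph(
  data.frame(id = 1:10, name = paste0("v", 1:10)),
  rbind(cl(1:5), cl(6:10), data.frame(source = 5, target = 6)))
louvain(two_cliques, seed = 1, restarts = 5)
```

## Random baselines for topology claims

Claims like "this map is small-world-like" or "its degree distribution is
heavy-tailed" need a reference point. `compare_to_random()` builds an
ensemble of uniform directed $G(N, E)$ graphs with matched node and edge
counts and reports each observed metric as a z-score. The uniform null is
deliberate: a degree-preserving null would build the observed hubs into
the baseline and erase the very signal being tested.

The heavy-tail rule — observed maximum degree more than 3 ensemble
standard deviations above the ensemble mean — is a declared convention of
this package, not an inferential test, and no power-law exponent is fitted:
with maximum degrees around 14, any exponent estimate would be noise.
When every ensemble graph is identical (e.g. a complete graph) the sd is
zero and z-scores are reported as `NA` rather than inventing a number.

## The synthetic CLD generator

Published CLD data is rarely redistributable, so the package ships seeded
generators that make every stage testable:

* `er_directed(n, m, seed)` — uniform simple directed graphs, the baseline
  null.
* `preferential_attachment_directed(n, k, seed)` — arrival process with
  `in-degree + 1` attachment (the +1 keeps zero-in-degree variables
  reachable as targets), producing heavy in-degree tails.
* `cld_like(seed)` — a 114-variable, 209-link network emulating the
  statistical signature of a community-built childhood-obesity CLD.

`cld_like()` is constructive rather than fitted. It plants, at fixed IDs:
exactly one isolate (47); in-degree hubs of 14, 13, 11 and 7 (IDs 66, 84,
57, 26); out-degree hubs of 7 and 6 (IDs 8 and 98, with 8 and 102 as
zero-in-degree root influencers); a three-variable reinforcing loop
64 → 88 → 84 → 64; a 16-hop geodesic chain from 113 to 77 that realises
the diameter at that exact pair; and five modular blocks holding the
remaining variables, with most filler links placed within blocks. A seeded
greedy rewiring pass then walks the average path length into the window
[4.645, 4.655] (so it reports as 4.65) and the planted-partition
modularity into a window calibrated so that 20-restart Louvain lands in
0.56 ± 0.03 — the emulation targets for the study-scale system. Draws
that cannot satisfy every constraint are rejected and re-drawn from a
derived seed, with diagnostics if the retry budget is exhausted.

What the generator does *not* emulate is as important for interpreting
test results:

* Variable names are synthetic labels; nothing semantic attaches to them.
* The betweenness *profile* is whatever the construction induces. Global
  betweenness values are functionals of the entire wiring, and no
  generator can plant a specific score such as "804.6 at ID 64"; tests of
  betweenness therefore validate the algorithm against exhaustive oracles
  rather than against published magnitudes.
* Polarity is uniformly `"unknown"`; real maps carry signs.
* Real CLDs have idiosyncratic meso-structure (chained themes, shared
  membership between clusters) that five clean blocks do not capture.

Passing tests on `cld_like()` graphs therefore demonstrate that the
pipeline measures what it claims to measure on data with the right
statistical shape — not that any particular community's map has these
properties.

## Verification strategy and problem sizes

Every algorithm is checked against an independent oracle that takes a
different route: BFS distances against boolean matrix-power walks;
Brandes betweenness against exhaustive enumeration of all shortest paths
(distance-pruned DFS) on ~100 random graphs of up to 15 nodes, exact to
1e-9, and against igraph; modularity against igraph on random partitions
and against exhaustive sweeps over all set partitions on up to 8 nodes
(Bell(8) = 4140); Louvain against exhaustive optima (within 0.05 on tiny
graphs, exact on planted two-clique and disjoint-cycle instances); loop
enumeration against brute-force permutation search on up to 7 nodes.
These sizes keep the full suite comfortably inside a few minutes on one
CPU while leaving the oracles genuinely exhaustive.

## Known limitations

* Polarity-aware analysis (loop classification as reinforcing/balancing,
  signed centrality) is stored-but-unused by design.
* No weighted edges, no delays: the CLD grain is binary causal assertion.
* Community detection is single-membership and single-level in its output;
  no overlapping or hierarchical communities.
* The small-world comparison uses density plus path length only; directed
  clustering-coefficient indices (σ, ω) involve convention choices on
  directed multigraphs that add heat without light at this scale.
* `compare_clds()` matches variables by normalized name (lowercase,
  punctuation stripped, whitespace collapsed). Synonym or semantic
  matching across communities' vocabularies is out of scope.
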