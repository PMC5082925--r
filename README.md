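# cldnet — network analysis of causal loop diagrams

Community groups tackling complex public-health problems (childhood
obesity being the canonical case) increasingly build **causal loop
diagrams (CLDs)** through group model building: systems maps in which
variables are connected by directed causal arrows. A community CLD with a
hundred-plus variables encodes far more structure than can be judged by
eye, yet it is exactly the artifact from which intervention decisions are
made.

cldnet turns a CLD into numbers. It represents the diagram as a directed,
unweighted, simple graph with adjacency $x_{ij} \in \{0,1\}$ and computes,
from scratch and with deterministic tie-breaking:

- **Global topology** — density $E/(N(N-1))$; in/out degree
  distributions; average directed shortest-path length over reachable
  ordered pairs; diameter with its achieving pair; isolate count.
- **Node centrality and leverage points** — in-degree (widely-caused
  variables), out-degree (widely-acting variables), Brandes betweenness
  $C_B(v)=\sum_{s\ne v\ne t}\sigma_{st}(v)/\sigma_{st}$ (the mediators),
  ranked tables, and root influencers (in-degree 0, positive out-degree).
- **Communities** — hand-rolled multilevel greedy (Louvain-style)
  modularity optimisation with seeded restarts, plus modularity scoring in
  undirected-projection and directed variants.
- **Feedback loops** — bounded enumeration of simple directed cycles,
  canonically rotated, filterable through a variable of interest.
- **Topology baselines** — comparison against seeded uniform $G(N,E)$
  ensembles with z-scores, quantifying "small-world-like" and
  "heavy-tailed" claims instead of asserting them.
- **Synthetic data** — seeded generators (`er_directed`,
  `preferential_attachment_directed`, `cld_like`) so the whole pipeline is
  testable without restricted study data; `cld_like()` emulates the
  statistical signature of a real community obesity CLD (114 variables,
  209 links, one isolate, planted hubs and loop, diameter 16, average
  path length 4.65, modularity ≈ 0.56).
- **Reporting** — `analyze_cld()` end-to-end bundles (JSON/CSV/GraphML,
  byte-reproducible given the same seed), `compare_clds()` for
  cross-community comparison by normalized variable name with Spearman
  rank correlation of centralities, and a thin CLI at
  `inst/cli/cldnet.R`.

## Worked example

```r
library(cldnet)

g <- cld_like(seed = 7)            # or build_graph(read_variable_key(...),
g                                  #                read_edge_list(...))
#> <cld_graph> 114 variables, 209 causal links, 1 isolate(s)

global_report(g, seed = 1, restarts = 20)
#> <cld_global_report>
#>  nodes edges density avg_path_length modularity diameter diameter_source
#>    114   209   0.016            4.65       0.57       16             113
#>  diameter_target n_isolates n_reachable_pairs
#>               77          1              2685
```

The one-row report reads: 114 variables and 209 causal links give density
0.016 — only 1.6% of the possible causal relations were asserted, so the
map is sparse and interventions must seed change in several places. The
average causal chain between connected variables is 4.65 links (short:
influence spreads efficiently), while the longest minimum chain runs 16
links from variable 113 to variable 77 — too long to trust. Modularity
0.57 says the map organises into distinct thematic clusters, which makes
the high-betweenness bridges between them prime leverage points.

```r
top_central(centrality_table(g), "in_degree", 4)[, c(1:3, 5)]
#>    id                   name in_degree betweenness
#> 66 66 synthetic-variable-066        14    435.5833
#> 84 84 synthetic-variable-084        13    601.7333
#> 57 57 synthetic-variable-057        11    369.1667
#> 26 26 synthetic-variable-026         7      0.0000

find_feedback_loops(g, max_length = 3, through = 88)
#> [[1]]
#> [1] 64 88 84

head(root_influencers(g), 4)
#> [1]   8 102 109   6
```

Variable 66 is the biggest hub (14 perceived causes); the loop
64 → 88 → 84 → 64 is a reinforcing feedback structure; variables 8 and
102 drive the system but nothing in the map feeds back into them — the
community has no mapped handle on them.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/cldnet.R generate --kind cld_like --seed 7 --out map/
Rscript inst/cli/cldnet.R analyze --key map/key.csv --edges map/edges.csv \
        --polarity-col polarity --out results/ --baseline 15
```

## Scope

Polarity is parsed and preserved but used by no metric: signed analysis
(reinforcing vs balancing loops) is deliberately deferred. No layout or
visualisation — export to GraphML/DOT and use a dedicated viewer. See the
vignette (`vignettes/cld-network-analysis.Rmd`) for the methods account:
conventions, parameter defaults, generator design, oracle strategy, and
limitations.
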