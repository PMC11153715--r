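---
title: "Radiate analysis and influence tracing: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiate analysis and influence tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgradiate)
```

## The model

`kgradiate` treats a curated pathway database as a directed property
multigraph: entities (small molecules, proteins, complexes), reactions and
pathways are typed nodes; relationships such as `input`, `output`,
`catalyst` or `positivelyRegulates` are typed edges. Sub-cellular
compartments are node properties, not separate nodes, so the same
metabolite can exist as distinct cytosolic and extracellular instances.

Given a source set $S$ (e.g. differential plasma metabolites resolved to
their extracellular instances), **radiate analysis** scores every node by
personalized PageRank: the stationary distribution of a random walk that,
with probability $d$, follows an out-edge uniformly (parallel edges count
by multiplicity) and, with probability $1-d$, teleports to a uniformly
chosen source. Walkers at dangling nodes (no out-edges) are also
redistributed along the teleport vector. Forward analysis uses the edge
directions as given; reverse analysis runs the identical computation on
the edge-reversed graph — in this package the reverse code path *is* the
forward code path applied to `reverse_edges(g)`, which makes the
directional contract exact by construction rather than by test.

**Tracing** then connects sources to chosen top-ranked targets. Hop mode
returns all minimum-edge-count paths. Influence mode first weights every
edge by $w(u,v) = 1/\max(\pi(u), \pi(v), \epsilon)$ and returns all
minimum-total-weight paths; a 3-step route through high-score nodes can
beat a 2-step route through a near-zero node, which is the intended
behavior — the trace follows influence, not geometry. The union of
returned paths forms the trace graph exported as Sankey JSON.

## Assumptions

* Influence is adequately modeled by a memoryless random walk; edge types
  are not differentially weighted beyond the traversable / non-traversable
  dichotomy.
* The graph's curated directionality is meaningful: forward and reverse
  analyses are distinct questions, not symmetrizations.
* Currency metabolites carry no pathway-specific information, so removing
  them sacrifices nothing the analysis should see.

## Tunable parameters

| parameter | default | unit / range | why this default |
|---|---|---|---|
| `damping` | 0.85 | probability | the standard PageRank convention of the reference implementation; the method itself fixes no value |
| `tol` | 1e-10 | L1 change per iteration | well below score differences that affect ranking on graphs up to millions of nodes |
| `max_iter` | 1000 | iterations | power iteration at d = 0.85 converges in O(100) iterations; 1000 leaves a wide margin, and non-convergence is flagged, never silent |
| `epsilon_floor` | 1e-12 | score floor | keeps inverse weights finite for unreached nodes so connectivity is preserved instead of dropping edges |
| `rel_tol` (influence tracing) | 1e-9 | relative cost slack | weighted minimality is a floating-point comparison; ties must be recognized as ties |
| `max_paths` | 10000 | per (s, t) pair | bounds combinatorial blow-up; truncation sets a flag |
| `top_k` | user choice | nodes | how many ranked nodes feed tracing/enrichment is an analyst decision with no principled default |
| `alpha` | 0.05 | q-value threshold | conventional FDR significance level |

## Numerical choices

* **Renormalization.** PageRank is stochastic up to floating-point drift;
  scores are divided by their sum after convergence so the sum-to-one
  invariant holds to 1e-9 by construction, even for unconverged results.
* **Tie-breaking.** Node rankings break score ties by ascending node id;
  path sets are ordered by (source, target, length, lexicographic node
  sequence); all table and JSON outputs are sorted so reruns are
  byte-stable.
* **Dangling mass.** Redistributed proportionally to the teleport vector,
  matching the cited reference implementation. This materially changes
  reverse-analysis results (the reversed graph has different sinks), so it
  is fixed behavior, not a knob.
* **Degenerate inputs.** A source equal to a target yields the zero-length
  path; unreachable pairs are recorded, not errors; an empty trace is a
  valid (warned) output; an empty effective enrichment query returns an
  empty table.

## Statistics

Enrichment of a query gene set against an annotation universe of size $N$
uses the one-sided Fisher exact test: for a term annotating $K$ background
genes with $k$ hits in a query of size $n$, $p = P(X \ge k)$ for
hypergeometric $X$. One-sidedness is a deliberate choice — "enriched"
is a directional claim, and the two-sided test would change q-value lists.
Only terms with $k \ge 1$ are tested, and the Benjamini–Hochberg
multiplicity $m$ is the number of tested terms; both choices affect $q$
and are therefore fixed and documented rather than configurable defaults.
No ontology ancestor propagation is performed: annotations are taken as
given.

The dictionary matcher is a transparent stand-in for a full rule-based
entity-recognition system: leftmost-longest, non-overlapping matches
anchored at token boundaries, case-insensitive for terms of ≥ 4 characters
and case-sensitive for shorter symbols (so `SRC` does not fire on "src").
Its output is deterministic, which is what the downstream counting
(entity clouds) and gene-set closure (semantic expansion) need from it.

## The synthetic world

The generator plants `n_cascades` disjoint signaling cascades

```
ligand --input--> binding reaction --output--> ligand:receptor complex
  --catalyst--> phosphorylation --output--> kinase ... --positivelyRegulates--> TF
```

with, by default, six cascades (mirroring a six-metabolite input set),
four kinase steps each, an ATP hub wired as input/output to eight
reactions across cascades, a ubiquitin regulator, bystander extracellular
metabolites, and Person/Affiliation/Taxon plus mouse-protein decoys for
preprocessing to remove. Extra random edges are placed only downstream of
cascade endpoints (terminal kinases and TFs fan out to bystander
metabolites through export reactions): this keeps each planted
ligand-to-TF route *unique by construction*, so planted-path recovery is a
well-defined ground truth rather than a probabilistic one. All randomness
flows through one seed; identical specs yield byte-identical files.

What a green test does establish: the propagation, weighting, tracing,
filtering and statistics behave exactly as specified on graphs with the
structural motifs the method targets, including the currency-shortcut
artifact (with exclusion off, shortest paths do route through the ATP
hub; with exclusion on, flagged nodes never appear on any path).

What it does not establish: behavior at the scale and degree distribution
of a real pathway database (millions of nodes, heavy-tailed hubs),
robustness to curation noise, or the biological validity of any ranked
hypothesis. Reproducing the published processed-graph size requires the
real database download and stays outside the offline suite.

## Design decisions that were genuinely open

* **Node lookup convention.** Compartment-specific instances of one
  molecule are matched by id prefix (`BASE.compartment` ids) with a
  preference for the requested compartment, defaulting to the
  extracellular region; a lone instance elsewhere is returned with a
  warning rather than dropped, because silently losing a source biases
  propagation more than a compartment mismatch does.
* **Traversable edge types and currency list.** Both canonical lists live
  in supplementary material of the upstream project rather than in any
  standard; the package ships sensible defaults
  (`default_traversable_edge_types()`, `default_currency_names()`) and
  treats both as configuration. Edge-*addition* rules default to empty for
  the same reason.
* **Multigraph semantics.** Parallel typed edges collapse, for the random
  walk, into one transition weighted by multiplicity; for path finding,
  into the single cheapest transition (a path is a node sequence). The
  alternative — treating each typed edge as a separate path — would
  multiply path counts without changing any node sequence.
* **Sankey dialect.** Index-based nodes/links JSON, the de facto
  plotly/d3 convention, documented field by field, because the upstream
  file format is internal.
* **Empty-`n_terms` annotation sets.** `generate_annotations(n_terms = 0)`
  disables the planted term too and returns an empty set; planting into an
  otherwise empty universe would make the "empty" case not empty.

## Known limitations

* The DFS path enumerator is exact but exponential in the worst case;
  `max_paths` bounds work per pair, and dense graphs with many near-ties
  should use hop mode or a tighter `rel_tol`.
* Reverse analysis on graphs with many sinks concentrates dangling mass on
  the sources; rankings near the sources should be read with that in mind.
* The entity recognizer has no disambiguation: a surface form maps to one
  concept id per dictionary row, first (longest) entry wins.
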