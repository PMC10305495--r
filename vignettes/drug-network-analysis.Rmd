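---
title: "Protein–drug networks and off-target profiling with dtnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protein–drug networks and off-target profiling with dtnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtnet)
```

## The problem

A drug's side effects are, to a large extent, network effects. Beyond its
intended receptor, a drug sits in a neighborhood of proteins that
physically interact with that receptor — its *first neighbors* in the
binary protein–protein interactome. Those neighbors are the natural
candidate set for off-target interactions: they are physically adjacent to
the drug's site of action, they are often co-regulated or co-complexed
with the target, and other drugs that bind them create indirect
drug–drug-interaction liabilities. dtnet implements this first-neighbor
analysis as a reusable pipeline over flat-file snapshots of the kind
exported by drug–target databases (DrugBank-style tables), interactome
resources (PICKLE-style UniProt-level edge lists), GO annotation sets,
gene–disease association tables (DisGeNET-style scores) and per-protein
proteoform records.

## The model and its stages

**Network construction.** The interactome is an undirected, unweighted
graph over protein accessions; self-pairs (homodimers) are stored as
edges but flagged. For a set of focal drugs, the protein–drug network
contains: the focal drugs (optionally collapsed to one node per drug
class), their targets, the targets' first neighbors, and every other drug
in the table that binds an included protein. `binds` edges connect drugs
to proteins; `ppi` edges are the *full induced subgraph* on the included
proteins — neighbor–neighbor edges are kept, because subnetwork edge
counts in this style of analysis exceed the pure target–neighbor star.
Expansion is strictly one hop: neighbors of neighbors are never pulled
in. A protein is never its own first neighbor, so a self-pair at the
target contributes an edge but not a neighbor.

**Topology.** Degree, betweenness, closeness, and the
eccentricity extrema (diameter, radius) describe the resulting graphs.
Distances treat `binds` and `ppi` edges as equally traversable and ignore
self-pairs.

**Neighborhood similarity.** Two drug networks are compared by the
Jaccard index of their protein sets: with shared count $M_{11}$ and
one-sided counts $M_{10}, M_{01}$,

$$J = \frac{M_{11}}{M_{11}+M_{10}+M_{01}}, \qquad d_J = 1 - J.$$

$J$ is a proxy for how much of one drug's off-target space another drug
shares. The Tanimoto coefficient on molecular fingerprints is the same
statistic applied to structural feature sets, and `tanimoto()` /
`neighbor_jaccard()` coincide on identical id sets (tested literally).

**Over-representation.** Each annotation term is tested individually
(term-for-term, no ontology propagation) with the hypergeometric upper
tail $P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$; the
one-sided Fisher exact test is provided as the mathematically identical
alternative route. Benjamini–Hochberg adjustment is applied across all
terms tested in the run (one family per run), and fold enrichment is
$(k/n)/(K/N)$, rendered as ">100" above 100 in reports.

**Profiles.** Proteoform totals sum three sources — PTM events, allelic
variants, splice transcripts. PTM category breakdowns pool events over a
protein set and report percentages rounded half-up at two decimals.
Disease rankings aggregate gene–disease scores per disease (maximum by
default) and sort descending with label tie-breaks.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `organism` | `"HUMAN"` | only rows with this organism label enter network construction; viral target rows stay out of human builds |
| `self_loops` (degree) | `"single"` | a self-pair adds 1 to degree ("interacts with itself, counted once"); `"double"` gives the graph-theoretic convention |
| `normalized` (betweenness) | `FALSE` | unnormalized pair counts by default; `TRUE` scales by $2/((n-1)(n-2))$ |
| `include_targets` | `TRUE` | drug neighborhood sets used for Jaccard comparisons include the targets themselves as well as their neighbors |
| `alpha` | 0.05 | FDR threshold below which a term is flagged as displayed |
| `annotated_only` | `FALSE` | background is every supplied gene, annotated or not; `TRUE` restricts to annotated genes |
| `aggregate` (diseases) | `"max"` | a single strong gene–disease association should surface; `"mean"` available |

## Design choices where the design was open

- **Closeness on disconnected graphs** uses the component-scaled form
  $(r/\sum d) \cdot (r/(n-1))$ for a node reaching $r$ others; isolated
  nodes score 0. This keeps values in $[0,1]$ and comparable across
  components.
- **Diameter and radius** are computed on the largest connected
  component and reported together with the component count, so the
  restriction is visible to the caller.
- **Zero-denominator Jaccard** (two empty sets) is an error by default
  rather than silently 0; an explicit `zero_if_empty` flag opts into the
  zero convention. An empty union almost always indicates an input
  problem.
- **Fingerprints** use a deterministic path-based scheme: all linear
  atom–bond paths of 1–7 bonds (plus single-atom features),
  canonicalized by reading direction and hashed with a 31-ary polynomial
  string hash into 31-bit ids. The scheme is self-consistent and
  documented rather than a reimplementation of any particular external
  workbench, so absolute Tanimoto values are comparable only within the
  scheme.
- **Enrichment ordering** is deterministic: rows sort by
  $(p, q, \text{term id})$. The report carries both the full ordering
  and the `displayed` flag (FDR < alpha), so "top by p" and "FDR-passing"
  views are both recoverable from one table.
- **Group collapse** unions the member drugs' binds edges into a single
  drug-group node: two members binding the same target collapse to one
  group edge (a deduplicated union, not a multiset).
- **BH reapplication**: the step-up adjustment is not idempotent in
  general (re-adjusting adjusted values can raise plateaus), so the
  property suite asserts dominance (`bh_fdr(q) >= q`) together with
  monotonicity and the cap, not fixed-point behavior.

## The synthetic-data generator

Real snapshots of the source databases are large, versioned and not
redistributable, so dtnet ships generators whose outputs have *exact*
ground truth:

- `simulate_interactome()` grows a preferential-attachment graph (each
  new node attaches to `pa_m = 2` existing nodes with probability
  proportional to degree + 1), because real interactomes are hub-
  dominated; an Erdős–Rényi-like flat degree profile would make the
  hub-target scenarios untestable. A configurable 2% of proteins get a
  self-pair, emulating homodimers. Two planted target nodes are wired to
  a shared pool and private pools whose sizes realize a requested
  neighbor-overlap Jaccard *exactly by construction* — overlap is not
  sampled, so comparison counts are exact acceptance oracles.
- `simulate_drug_targets()` emits a drug class sharing one hub target
  (with a couple of members carrying a second target, as real drug
  classes do), one drug per planted target, singleton drugs (half on hub
  neighbors, so `other_drug` nodes arise), and one non-human target row
  to exercise the organism filter.
- `simulate_annotations()` draws uniform background terms (the null
  model) and, when requested, plants one term whose study-set count
  $k = \mathrm{round}(\text{fold} \cdot n K / N)$ achieves the requested
  fold exactly up to integer rounding; unachievable requests are
  rejected rather than approximated.
- `simulate_proteoforms()` and `simulate_diseases()` use multinomial
  PTM categories (weights defaulting to a modified-residue-dominated
  mixture), Poisson allelic/splice counts, and uniform disease scores
  with one planted dominating disease at score 0.99.

Every generator is a pure function of the seed. What the generator does
*not* emulate: biological correlation between annotations and topology,
realistic GO term hierarchies, literature-biased interactome coverage,
or the actual degree distributions of any database release. Passing the
ground-truth closure tests therefore demonstrates that the pipeline's
set arithmetic, statistics and bookkeeping are correct — not that its
biological conclusions transfer to any particular database snapshot.

## Validation scale and numerical notes

The test suite validates centralities, eccentricities and neighbor
extraction against brute-force oracles (exhaustive simple-path
enumeration) on 200 random graphs of up to 8 nodes, and the
hypergeometric tail against full enumeration of all $\binom{N}{n}$ draws
for every valid margin with $N \le 12$. Statistical calibration uses
1,000 null-annotation replicates (200 proteins, 30 terms) and 500
planted-signal replicates (1,000 proteins, fold 5, study size 20); the
pipeline closure test runs the default generator scale of 1,000 proteins
and 40 drugs. These sizes were chosen so the oracles stay exhaustive
(and therefore trustworthy) while the stochastic checks have enough
replicates for tight binomial error bounds.

The hypergeometric tail is evaluated through R's stable upper-tail
routine rather than by summing densities; percentages round half-up
(`floor(100x + 0.5)/100`) to match two-decimal report style; all report
tables are sorted deterministically, so reruns with an identical
manifest are byte-identical.

## A worked example

```{r example}
cfg <- sim_config(seed = 7)   # 1,000 proteins, 40 drugs
snap <- simulate_snapshot(cfg, file.path(tempdir(), "snapshot"))

res <- run_pipeline(list(
  ppi = snap$paths$ppi, drug_targets = snap$paths$drug_targets,
  annotations = snap$paths$annotations, diseases = snap$paths$diseases,
  proteoforms = snap$paths$proteoforms,
  focal_groups = list(GroupA = "DRGA", GroupB = "DRGB"),
  out_dir = file.path(tempdir(), "report")))

res$comparisons
head(res$enrichment$GroupA[, c("term", "fold_enrichment", "p", "q")], 3)
res$diseases$GroupA$disease[1]
```

The comparison row reflects the planted overlap exactly
(`snap$gt$comparison_with_targets`), the planted term tops the
enrichment table, and the planted disease tops the ranking.

## Known limitations

- Absolute network sizes, mean degrees and structural-similarity ranges
  are snapshot- and scheme-dependent; dtnet reproduces published
  *count-derived* statistics (Jaccard rows, percentage breakdowns) and
  validates everything else by construction, but does not attempt to
  reproduce any particular database release.
- No identifier mapping: inputs must already be keyed by consistent
  accessions.
- Annotations are used as given; GO ancestor closure, evidence-code
  filtering and term hierarchies are input-preparation concerns.
- Shortest-path measures are unweighted; confidence-scored interactomes
  are flattened to binary edges at ingestion.
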