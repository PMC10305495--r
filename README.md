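# dtnet

Protein–drug network construction and off-target profiling in R.

## What problem this solves

Most side effects are network effects: a drug's intended receptor sits
inside a neighborhood of proteins it physically interacts with, and those
**first neighbors** are the natural candidates for off-target
interactions. `dtnet` is for computational biologists who have flat-file
snapshots of a drug→target table (DrugBank-style), a binary
protein–protein interactome at the accession level (PICKLE-style), and
optionally GO annotations, gene–disease scores (DisGeNET-style) and
proteoform records — and who want, offline and reproducibly:

1. the heterogeneous **protein–drug network** around a set of focal drugs
   (drugs + targets + first neighbors + every other drug binding them);
2. its **topology** — degree, betweenness, closeness, diameter/radius;
3. **neighborhood similarity** between drug networks via the Jaccard
   index, and **structural similarity** between molecules via the
   Tanimoto coefficient on path-based fingerprints;
4. **term-for-term over-representation** of the neighbor sets
   (hypergeometric / one-sided Fisher exact, Benjamini–Hochberg FDR,
   fold enrichment);
5. **proteoform breakdowns** (PTM categories, allelic variants, splice
   transcripts) and **disease rankings** for targets and neighbors.

The core statistic for comparing two drugs' off-target spaces is the
Jaccard index of their protein sets: with shared count M11 and one-sided
counts M10, M01,

```
J = M11 / (M11 + M10 + M01),    dJ = 1 − J
```

and the Tanimoto coefficient is the same statistic on fingerprint
feature sets. Over-representation of an annotation term with K carriers
in a background of N, given k carriers in a study set of n, is the
hypergeometric upper tail P(X ≥ k), with BH adjustment across all terms
tested.

A seeded synthetic-data module generates complete input snapshots with
*exact* ground truth (planted neighbor overlaps, a planted enriched term,
a planted top disease), so the entire pipeline is testable without any
database access.

## Worked example

```r
library(dtnet)

cfg  <- sim_config(seed = 7)                       # 1,000 proteins, 40 drugs
snap <- simulate_snapshot(cfg, "snapshot")

res <- run_pipeline(list(
  ppi          = snap$paths$ppi,
  drug_targets = snap$paths$drug_targets,
  annotations  = snap$paths$annotations,
  diseases     = snap$paths$diseases,
  proteoforms  = snap$paths$proteoforms,
  focal_groups = list(GroupA = "DRGA", GroupB = "DRGB"),
  out_dir      = "report"))

res$comparisons
#>   label_a label_b m11 m10 m01         j        dj
#> 1  GroupA  GroupB  20  11  11 0.4761905 0.5238095
```

The two focal drugs were planted with a neighbor-overlap Jaccard of 0.5
over a 40-protein union; including each drug's own target, the pipeline
recovers 20 shared and 11+11 private proteins, J = 20/42 ≈ 0.476 —
exactly the generator's bookkeeping.

```r
head(res$enrichment$GroupA[, c("term", "fold_enrichment", "p", "q")], 2)
#>         term fold_enrichment            p           q
#> 1 GO:PLANTED        5.171613 7.138127e-05 0.003640445
#> 2 GO:SIM0033        3.513324 1.132030e-02 0.288667754

res$diseases$GroupA$disease[1]
#> [1] "PlantedDisease"

res$summaries$GroupA
#> 33 nodes, 34 edges (0 self-pairs); diameter 3, radius 2, 1 component(s)
```

The planted fold-5 term tops the enrichment table and is the only one
flagged at FDR < 0.05; the planted disease tops the ranking. Published
comparison counts can be replayed directly:

```r
jaccard_from_counts(17, 303, 11)
#> $j
#> [1] 0.05135952
#> $dj
#> [1] 0.9486405
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/dtnet` (subcommands `simulate`, `validate`, `run`,
`compare-counts`, `tanimoto`, `metrics`).

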