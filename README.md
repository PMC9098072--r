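# immunet

Metabolite–immune process association networks.

## What problem this solves

Interpreting metabolomics data in terms of immune function is hard:
metabolites, unlike proteins, carry almost no functional annotation.
`immunet` is for researchers in immunometabolomics who want to ask
either "which metabolites are associated with this immune process?"
(to guide the design of a targeted metabolomics panel) or "which
immune processes is this metabolite associated with?" (to interpret a
hit). It answers both by building a protein–metabolite interaction
network from database-style tables and letting metabolites *inherit*
the Gene Ontology immune-process annotations (descendants of
GO:0002376) of nearby proteins.

## The method

An atlas database merges five inputs: GO-style immune-process terms,
a protein catalog with process annotations, a metabolite catalog
(filtered to biological, non-inorganic compounds), STRING-style scored
protein–protein interactions (kept at combined score ≥ 400 by
default), and Rhea-style reactions expanded all-versus-all into
metabolite–metabolite edges. Metabolite–protein edges keep only
proteins with immune annotations. On a query network, each inherited
(metabolite *i*, process *j*) pair is scored by:

- **harmonic closeness** — Σ<sub>j≠i</sub> 1/d(i,j), normalized by
  n−1; well-defined on disconnected graphs, equal for metabolites with
  identical neighbour sets;
- **precision** — N<sub>ij</sub>/N<sub>i</sub>, the fraction of the
  metabolite's database interactions that lie inside the process
  network (1.00 = fully committed); an alternative mode divides by the
  process network size V<sub>j</sub>;
- **Fisher overrepresentation** (one-sided by default) of the
  metabolite's neighbourhood inside the network against the atlas
  background, with Benjamini–Hochberg FDR pooled per run
  (significance at q < 0.05);
- **biomarker flags** for significant pairs exceeding mean + 2 SD of
  the significant set on both centrality and precision.

Inheritance order k (1–3) means one metabolite–protein step plus up to
k−1 protein–protein steps; metabolite–metabolite edges never transmit
annotations. Predicted pair sets are nested in k, so evaluating
against a literature-derived gold standard (pairs with ≥ 2
occurrences, lipids excluded) shows the characteristic trade-off:
direct inheritance is more precise, indirect more sensitive
(specificity/sensitivity/precision/accuracy/F1, with
F1 = TP/(TP + ½(FP+FN))).

## Worked example

The packaged miniature atlas mimics a positive-regulation-of-T-cell-
mediated-immunity query:

```r
library(immunet)
atlas <- loadTcellToy()
atlas
#> AtlasDB
#>  processes:   4
#>  proteins:    9
#>  metabolites: 9
#>  edges:       37 (PPI 7, PMI 28, MMI 2)

net <- buildProcessNetwork(atlas, "GO:0002711")
net
#> InteractionNetwork (by_process query, order 1)
#>  nodes: 14 (6 proteins, 8 metabolites)
#>  edges: 28
#>  isolated proteins: 1

tab <- rankAssociations(atlas, net)
subset(tab, process_id == "GO:0002711",
       select = c(metabolite_id, centrality, precision, p, q))
#>   metabolite_id centrality precision     p     q
#> 1          MB05      0.526      1.00 0.421 0.912
#> 2          MB06      0.526      0.80 0.670 0.912
#> 3          MB01      0.526      0.75 0.781 0.912
#> 4          MB02      0.526      0.75 0.781 0.912
#> 5          MB03      0.526      0.75 0.781 0.912
#> 6          MB04      0.526      0.75 0.781 0.912
#> 7          MB07      0.487      0.75 0.781 0.912
#> 8          MB08      0.487      0.75 0.781 0.912
```

The process network holds exactly 8 metabolites. The five co-attached
sphingoid-like metabolites (MB01–MB05) share one centrality value,
0.526, because they interact with the same three proteins; MB05, which
has no interaction outside the process, reaches precision 1.00 and
ranks first. The toy background is tiny, so no q-value reaches
significance here; seeded synthetic fixtures with a larger background
(`generateFixture()`) are where significance and biomarker flagging
come into play — see the methods vignette
(`vignettes/immunet-methods.Rmd`).

A command-line wrapper covers the same pipeline
(`inst/scripts/immunet`): subcommands `build`, `query-process`,
`query-metabolite`, `score`, `validate`, `simulate`, each writing its
tables plus a `run_summary.json` with input checksums and settings.

```sh
Rscript inst/scripts/immunet score \
  --manifest inst/extdata/tcell_toy/manifest.json \
  --mode process --ids GO:0002711 --out out/
```

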