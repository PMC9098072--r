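---
title: "Inferring metabolite-immune process associations with immunet"
author: "immunet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring metabolite-immune process associations with immunet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunet)
```

## The model

Metabolites rarely carry functional annotations of their own, while
proteins are richly annotated in the Gene Ontology. `immunet` transfers
immune-system annotations from proteins to metabolites across a
protein-metabolite interaction network. The background store (the
*atlas*, an `AtlasDB` object) merges five database-style tables: an
immune-process ontology (the descendants of *immune system process*,
GO:0002376), a protein catalog with process annotations, a metabolite
catalog with chemical taxonomy labels, STRING-style scored
protein-protein interactions (PPI), and Rhea-style reaction participant
lists expanded all-versus-all into metabolite-metabolite interactions
(MMI). Metabolite-protein edges (PMI) are derived from the metabolite
catalog's protein links, keeping only proteins that carry at least one
immune-process annotation. Metabolites must have a biological role and
must not be inorganic compounds; these filters emulate the exclusion of
synthetic drugs and minerals from curated metabolome databases.

All graphs are undirected: the underlying databases do not record the
direction of a protein-metabolite association, and we deliberately do
not invent one.

### Inheritance

A query network is built either *by process* (all proteins annotated to
the queried processes, plus their PMI metabolites, plus every PPI, PMI
and MMI edge among them) or *by metabolite* (the query metabolites plus
their PMI partners). Inheritance of order $k \in \{1,2,3\}$ then assigns
to each metabolite the annotations of every protein reachable by one PMI
edge followed by at most $k-1$ PPI edges. The PMI step counts as step
one, so "order 2" means two interaction steps. MMI edges never transmit
annotations: a metabolite connected only to other metabolites inherits
nothing. Intermediate proteins on an inheritance path contribute their
own annotations whether or not they belong to the queried process. For
metabolite queries at order $k > 1$ the network itself is expanded by up
to $k-1$ PPI hops beyond the direct partners, so the indirect neighbours
that inheritance needs are actually present; process-query networks are
kept fixed to the annotated protein set, which means second- and
third-order inheritance there traverses only in-process edges. The
alternative — following PPI edges out of the process — would mix the
query scope into the background and is intentionally not done.

### Scores

For every inherited (metabolite, process) pair the package computes:

* **Centrality** — harmonic closeness, $\sum_{j \ne i} 1/d(i,j)$ over
  unweighted shortest paths, with unreachable nodes contributing zero,
  which keeps the score well defined on the disconnected graphs these
  queries routinely produce. Scores are normalized by $n-1$ (the network
  size minus one), mapping them onto $[0,1]$; a singleton network scores
  0. Metabolites with identical neighbour sets are exchangeable under a
  graph automorphism and therefore receive exactly equal centralities.
* **Precision** — with $N_i$ the metabolite's interacting nodes in the
  whole atlas and $N_{ij}$ those inside the process-$j$ network, the
  default *ratio* mode is $N_{ij}/N_i$: the fraction of everything the
  metabolite can do (according to the database) that lies inside the
  process. A fully committed metabolite scores exactly 1.00. The
  *corrected* mode divides further by $V_j$, the process network's node
  count. The ratio is the default because a committed metabolite should
  be able to reach the maximal score regardless of process size; the
  corrected form is kept as an explicit mode for users who want to
  penalize large processes. A metabolite with $N_i = 0$ cannot be scored
  and is reported as missing.
* **Overrepresentation p-value** — a Fisher exact test contrasting the
  network against the database background. For a metabolite, the 2x2
  table asks whether its database neighbourhood is concentrated inside
  the process network: $a = N_{ij}$, $b = V'_j - N_{ij}$,
  $c = N_i - N_{ij}$ (the database-minus-network complement of its
  associations) and $d = (D - 1 - V'_j) - c$, where $D$ is the atlas
  node count and $V'_j$ excludes the metabolite itself. When the network
  is the whole atlas the complements vanish ($c = d = 0$) and $p = 1$ —
  there is no background left to be enriched against. This
  neighbourhood-based construction is used because a literal
  "associations in network vs. associations in database" count
  degenerates for exactly the metabolites the method is designed to
  highlight: a first-order process network contains every protein
  annotated to the process, so a fully committed metabolite would always
  have empty complements and $p = 1$, inverting the intended ranking
  (committed metabolites most significant, promiscuous hub metabolites
  least). For a process, the table contrasts its annotation instances in
  the network against those in the database, taken literally; this is
  not a disjoint 2x2 partition, so only self-consistency properties are
  claimed for it. The default alternative is one-sided (greater),
  matching an overrepresentation question; a two-sided option is
  available. P-values are computed from hypergeometric point
  probabilities in log space, so large tables do not overflow.
* **FDR** — Benjamini-Hochberg, pooled over all pairs of one network
  run; the significance flag is $q < 0.05$ by default.

Rows are ranked by $q$ ascending, ties broken by precision, then
centrality (descending), then ids, so output order is deterministic.

### Biomarker candidates

Among significant rows, candidates must exceed the mean plus
`sd_multiplier` (default 2) sample standard deviations of the
significant subset on **both** centrality and precision, with strict
inequality. With fewer than two significant rows the SD is undefined and
nothing is flagged; if all significant rows tie, the threshold equals
the common value and again nothing is flagged.

### Gold-standard evaluation

A literature-derived pair-count table is filtered: pairs observed only
once are removed (count 2 is the retention boundary), and pairs whose
metabolite belongs to an excluded superclass — typically *lipids and
lipid-like molecules*, whose nomenclature defeats text mining — are
removed regardless of count. Predictions from full-atlas inheritance at
each order are scored as TP/FP/FN/TN over the universe of all
(retained metabolite, immune process) pairs; this universe is the
natural background when the negative space is otherwise undefined, and
it is recorded in the run summary. Specificity, sensitivity, precision,
accuracy and $F_1 = TP/(TP + \tfrac12(FP+FN))$ follow; zero-denominator
ratios are reported as missing rather than zero. Because association
sets are nested across orders, sensitivity is non-decreasing and
specificity non-increasing in the order — the trade-off between direct
(precise) and indirect (sensitive) inheritance.

## Synthetic fixtures

`generateFixture()` emulates the five input schemas with planted
structure so the whole pipeline is testable without downloads. A single
integer seed drives base R's RNG, and identical seed + configuration
give byte-identical files on a given platform; the packaged T-cell toy
is checked in rather than generated, so it is identical everywhere.
The generator's layout:

* a random ontology tree under GO:0002376;
* immune proteins (default 60% of 80) annotated to 1-2 processes; each
  committed plant's target process receives a dedicated set of proteins
  (default 6) annotated *only* to that process, wired as a hub star;
* a PPI layer that is Erdős–Rényi over the immune proteins plus the
  hub stars — producing both connected hubs and disconnected
  singletons, which exercises the disconnected-graph behaviour of
  harmonic closeness;
* committed metabolites linked to every dedicated protein of their
  target process and nothing else (so their ratio precision is exactly
  1), plus a background cohort (default 9 metabolites with 3 in-process
  and 1-3 outside links) giving the significance machinery a realistic
  mid-field to rank the plant against;
* isolated metabolites with no protein links, synthetic-drug and
  inorganic rows that ingest must drop, and Poisson-linked fillers, some
  of which react with each other (the MMI layer).

Defaults (12 processes, 80 proteins, 60 metabolites, PPI density 0.04,
mean 2 PMI links) are small enough for sub-second generation yet large
enough that the atlas background ($D \approx 130$ nodes) separates
committed plants from the cohort statistically. What the generator does
**not** emulate: real HMDB/STRING degree distributions, annotation
depth, or correlated chemistry — passing the planted-recovery tests
shows the algorithms are implemented as specified, not that the method
will behave identically on the real databases.

## Numerical choices

* PPI confidences are STRING-style integers (0-1000); the default
  threshold 400 is STRING's "medium confidence" cut, exposed as
  configuration. Duplicate PPI rows keep the maximum score — a
  conservative, deterministic merge.
* Edge sets are canonical: lexicographically ordered endpoints, no
  self-loops, no duplicates; canonicalization is idempotent.
* Iteration is in lexicographic id order throughout, so supporting
  protein lists and tie-breaks are stable across runs.
* Floating-point table outputs are written with 6 significant digits,
  making repeated runs byte-identical.
* Two-sided Fisher p-values sum point probabilities not exceeding the
  observed one, with the same relative slack (1e-7) the standard R
  implementation uses against floating-point ties.
* Identifier namespaces are opaque strings; no accession checksums are
  validated.

## Problem sizes used in the test suite

Oracle comparisons run on every 2x2 table with margins up to 12
(enumeration is exact there), 200 random graphs of up to 50 nodes for
centrality, and random atlases of 10-16 proteins for inheritance;
nesting and trade-off properties are checked over 100 and 20-30 seeded
fixtures respectively. These sizes keep the full suite under a minute
while covering the degenerate shapes (disconnected graphs, empty
networks, all-zero tables) that matter.

## Worked example

```{r toy}
atlas <- loadTcellToy()
atlas
net <- buildProcessNetwork(atlas, "GO:0002711")
net
tab <- rankAssociations(atlas, net)
subset(tab, process_id == "GO:0002711",
       select = c(metabolite_id, centrality, precision, p, q))
```

The five sphingoid-like metabolites share one centrality value because
they attach to the same three proteins; the committed one scores
precision 1.00 and ranks first. The toy atlas is deliberately tiny
(18 nodes), so the Fisher background is weak and nothing reaches
significance — the generated fixtures, with their larger background,
are where significance and biomarker flagging are exercised:

```{r fixture}
dir <- tempfile()
fx <- generateFixture(fixtureConfig(seed = 42), dir)
fixAtlas <- readAtlas(file.path(dir, "manifest.json"), quiet = TRUE)
target <- fx$truth$committed[[1]]
ptab <- rankAssociations(fixAtlas,
                         buildProcessNetwork(fixAtlas, target$process_id))
selectBiomarkers(ptab)[, c("metabolite_id", "process_id",
                           "centrality", "precision", "q")]
```

## Limitations

* Associations are undirected and unweighted beyond the ingest
  threshold; no causal or stoichiometric reasoning.
* The overrepresentation background is the atlas itself, not the whole
  metabolome, so absolute p-values should be read comparatively.
* Second- and third-order inheritance in process queries stays inside
  the process network; neighbours outside the immune protein set are
  not traversed there.
* The process-based contingency table follows the literal
  network-versus-database appearance counts and is not a disjoint
  partition; treat its p-values as a ranking device.
* The gold-standard machinery evaluates whatever pair-count table it is
  given; building that table (literature mining) is out of scope.
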