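## In-memory atlas builders used across test files.

## Build an atlas directly from compact descriptions; all ids are opaque
## strings. `parents` maps term -> parent terms (root defaults to first).
makeAtlas <- function(parents,
                      annotations = list(),
                      metaboliteLinks = list(),
                      ppi = NULL, mmi = NULL,
                      root = names(parents)[1],
                      superclass = NULL) {
  termIds <- names(parents)
  ont <- processOntology(
    data.frame(term_id = termIds, name = paste("process", termIds)),
    parents = parents, root = root, quiet = TRUE)
  protIds <- names(annotations)
  prot <- proteinCatalog(
    data.frame(protein_id = protIds, name = paste("protein", protIds)),
    processes = annotations, ontology = ont, quiet = TRUE)
  metIds <- names(metaboliteLinks)
  if (is.null(superclass))
    superclass <- stats::setNames(rep("Organic acids and derivatives",
                                      length(metIds)), metIds)
  met <- metaboliteCatalog(
    data.frame(metabolite_id = metIds, name = paste("metabolite", metIds),
               class = "test class",
               superclass = unname(superclass[metIds]),
               is_biological = 1L, is_inorganic = 0L,
               compound_id = paste0("CPD_", metIds)),
    proteinLinks = metaboliteLinks, quiet = TRUE)
  ppiSet <- if (is.null(ppi)) edgeSet() else
    edgeSet(ppi[[1]], ppi[[2]], "PPI",
            if (ncol(ppi) >= 3) ppi[[3]] else 900L)
  mmiSet <- if (is.null(mmi)) edgeSet() else
    edgeSet(mmi[[1]], mmi[[2]], "MMI")
  pmiSet <- buildPMI(met, prot, quiet = TRUE)
  assembleAtlas(ont, prot, met, ppiSet, pmiSet, mmiSet)
}

## Random small atlas with a seeded layout; used for property tests.
randomAtlas <- function(seed, nProc = 4, nProt = 10, nMet = 8,
                        ppiProb = 0.25, mmiProb = 0.1) {
  set.seed(seed)
  terms <- c("GO:R", paste0("GO:T", seq_len(nProc)))
  parents <- c(list(character(0)), rep(list("GO:R"), nProc))
  names(parents) <- terms
  prots <- sprintf("P%02d", seq_len(nProt))
  ann <- lapply(prots, function(p) {
    if (stats::runif(1) < 0.25) character(0)
    else sample(terms[-1], sample(1:2, 1))
  })
  names(ann) <- prots
  mets <- sprintf("M%02d", seq_len(nMet))
  links <- lapply(mets, function(m) {
    k <- stats::rpois(1, 2)
    if (k == 0) character(0) else sample(prots, min(k, nProt))
  })
  names(links) <- mets
  pairs <- utils::combn(prots, 2)
  pick <- stats::runif(ncol(pairs)) < ppiProb
  ppi <- data.frame(a = pairs[1, pick], b = pairs[2, pick],
                    score = sample(400:999, sum(pick), replace = TRUE))
  mpairs <- utils::combn(mets, 2)
  mpick <- stats::runif(ncol(mpairs)) < mmiProb
  mmi <- data.frame(a = mpairs[1, mpick], b = mpairs[2, mpick])
  makeAtlas(parents, ann, links,
            ppi = if (nrow(ppi)) ppi else NULL,
            mmi = if (nrow(mmi)) mmi else NULL)
}

## Memoised packaged toy atlas.
.toyEnv <- new.env()
toyAtlas <- function() {
  if (is.null(.toyEnv$atlas)) .toyEnv$atlas <- loadTcellToy(quiet = TRUE)
  .toyEnv$atlas
}

## InteractionNetwork wrapper around an arbitrary igraph (all nodes
## treated as proteins unless kinds given); for centrality tests.
wrapNetwork <- function(g, kinds = NULL) {
  if (is.null(igraph::vertex_attr(g, "name")))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = paste0("N", seq_len(igraph::vcount(g))))
  if (is.null(kinds)) kinds <- rep("protein", igraph::vcount(g))
  g <- igraph::set_vertex_attr(g, "kind", value = kinds)
  if (igraph::ecount(g) > 0) {
    if (is.null(igraph::edge_attr(g, "edge_type")))
      g <- igraph::set_edge_attr(g, "edge_type", value = "PPI")
    if (is.null(igraph::edge_attr(g, "confidence")))
      g <- igraph::set_edge_attr(g, "confidence", value = 900L)
  }
  new("InteractionNetwork", graph = g, queryMode = "by_process",
      queryIds = character(0), order = 1L, isolatedProteins = character(0))
}

## Edge data.frame of an igraph in the canonical layout (for oracles).
graphEdges <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  data.frame(endpoint_a = el[, 1], endpoint_b = el[, 2],
             stringsAsFactors = FALSE)
}
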