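#' @importFrom igraph V E vcount ecount vertex_attr edge_attr degree
NULL

#' Accessors for atlas and network objects
#'
#' Small family of accessor generics; prefer these over direct slot access.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @return The requested component (see the individual generics).
#' @name accessors
NULL

#' @describeIn accessors data.frame of ontology terms (term_id, name).
#' @export
setGeneric("ontologyTerms", function(x, ...) standardGeneric("ontologyTerms"))
#' @describeIn accessors root term id of the ontology.
#' @export
setGeneric("ontologyRoot", function(x, ...) standardGeneric("ontologyRoot"))
#' @describeIn accessors named list of parent term ids.
#' @export
setGeneric("ontologyParents", function(x, ...) standardGeneric("ontologyParents"))
#' @describeIn accessors data.frame of proteins (protein_id, name).
#' @export
setGeneric("proteinTable", function(x, ...) standardGeneric("proteinTable"))
#' @describeIn accessors named list protein_id -> annotated process ids.
#' @export
setGeneric("processAnnotations", function(x, ...) standardGeneric("processAnnotations"))
#' @describeIn accessors data.frame of retained metabolites.
#' @export
setGeneric("metaboliteTable", function(x, ...) standardGeneric("metaboliteTable"))
#' @describeIn accessors named list metabolite_id -> linked protein ids.
#' @export
setGeneric("metaboliteProteinLinks", function(x, ...) standardGeneric("metaboliteProteinLinks"))
#' @describeIn accessors canonical edge data.frame.
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))
#' @describeIn accessors underlying igraph object.
#' @export
setGeneric("atlasGraph", function(x, ...) standardGeneric("atlasGraph"))
#' @describeIn accessors provenance data.frame (source, rows).
#' @export
setGeneric("provenanceTable", function(x, ...) standardGeneric("provenanceTable"))
#' @describeIn accessors igraph object of a query network.
#' @export
setGeneric("networkGraph", function(x, ...) standardGeneric("networkGraph"))
#' @describeIn accessors node ids of a query network, optionally by kind.
#' @export
setGeneric("networkNodes", function(x, ...) standardGeneric("networkNodes"))
#' @describeIn accessors annotated-but-unconnected proteins kept in a network.
#' @export
setGeneric("isolatedProteins", function(x, ...) standardGeneric("isolatedProteins"))
#' @describeIn accessors list(mode=, ids=, order=) describing the query.
#' @export
setGeneric("queryInfo", function(x, ...) standardGeneric("queryInfo"))

#' @rdname accessors
setMethod("ontologyTerms", "ProcessOntology", function(x, ...) x@terms)
#' @rdname accessors
setMethod("ontologyRoot", "ProcessOntology", function(x, ...) x@root)
#' @rdname accessors
setMethod("ontologyParents", "ProcessOntology", function(x, ...) x@parents)
#' @rdname accessors
setMethod("ontologyTerms", "AtlasDB", function(x, ...) x@ontology@terms)
#' @rdname accessors
setMethod("ontologyRoot", "AtlasDB", function(x, ...) x@ontology@root)
#' @rdname accessors
setMethod("ontologyParents", "AtlasDB", function(x, ...) x@ontology@parents)

#' @rdname accessors
setMethod("proteinTable", "ProteinCatalog", function(x, ...) x@proteins)
#' @rdname accessors
setMethod("processAnnotations", "ProteinCatalog", function(x, ...) x@processes)
#' @rdname accessors
setMethod("proteinTable", "AtlasDB", function(x, ...) x@proteins@proteins)
#' @rdname accessors
setMethod("processAnnotations", "AtlasDB", function(x, ...) x@proteins@processes)

#' @rdname accessors
setMethod("metaboliteTable", "MetaboliteCatalog", function(x, ...) x@metabolites)
#' @rdname accessors
setMethod("metaboliteProteinLinks", "MetaboliteCatalog", function(x, ...) x@proteinLinks)
#' @rdname accessors
setMethod("metaboliteTable", "AtlasDB", function(x, ...) x@metabolites@metabolites)
#' @rdname accessors
setMethod("metaboliteProteinLinks", "AtlasDB", function(x, ...) x@metabolites@proteinLinks)

#' @rdname accessors
setMethod("edgeTable", "EdgeSet", function(x, ...) x@edges)
#' @rdname accessors
setMethod("edgeTable", "AtlasDB", function(x, ...) x@edges@edges)
#' @param type optional edge type filter for network edge tables.
#' @rdname accessors
setMethod("edgeTable", "InteractionNetwork", function(x, type = NULL, ...) {
  df <- graphEdgeFrame(x@graph)
  if (!is.null(type)) df <- df[df$edge_type %in% type, , drop = FALSE]
  rownames(df) <- NULL
  df
})

#' @rdname accessors
setMethod("atlasGraph", "AtlasDB", function(x, ...) x@graph)
#' @rdname accessors
setMethod("provenanceTable", "AtlasDB", function(x, ...) x@provenance)

#' @rdname accessors
setMethod("networkGraph", "InteractionNetwork", function(x, ...) x@graph)
#' @param kind one of "all", "protein", "metabolite".
#' @rdname accessors
setMethod("networkNodes", "InteractionNetwork",
          function(x, kind = c("all", "protein", "metabolite"), ...) {
  kind <- match.arg(kind)
  nm <- igraph::vertex_attr(x@graph, "name")
  if (kind == "all") return(sort(nm))
  sort(nm[igraph::vertex_attr(x@graph, "kind") == kind])
})
#' @rdname accessors
setMethod("isolatedProteins", "InteractionNetwork", function(x, ...) x@isolatedProteins)
#' @rdname accessors
setMethod("queryInfo", "InteractionNetwork", function(x, ...)
  list(mode = x@queryMode, ids = x@queryIds, order = x@order))

## Edge data.frame (canonical) of an igraph built by this package.
graphEdgeFrame <- function(g) {
  if (igraph::ecount(g) == 0) return(emptyEdgeFrame())
  el <- igraph::as_edgelist(g, names = TRUE)
  canonicalizeEdges(el[, 1], el[, 2],
                    igraph::edge_attr(g, "edge_type"),
                    igraph::edge_attr(g, "confidence"))
}

#' Number of immune processes in the ontology of an atlas
#'
#' @param x an [AtlasDB-class] or [ProcessOntology-class].
#' @return Character vector of process term ids (including the root).
#' @export
immuneProcesses <- function(x) {
  ontologyTerms(x)$term_id
}

setMethod("show", "ProcessOntology", function(object) {
  cat("ProcessOntology with", nrow(object@terms), "terms; root",
      object@root, "\n")
})

setMethod("show", "ProteinCatalog", function(object) {
  nAnn <- sum(lengths(object@processes) > 0)
  cat("ProteinCatalog with", nrow(object@proteins), "proteins (",
      nAnn, "immune-annotated )\n")
})

setMethod("show", "MetaboliteCatalog", function(object) {
  cat("MetaboliteCatalog with", nrow(object@metabolites),
      "retained metabolites\n")
})

setMethod("show", "EdgeSet", function(object) {
  tab <- table(object@edges$edge_type)
  cat("EdgeSet with", nrow(object@edges), "edges (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
})

setMethod("show", "AtlasDB", function(object) {
  e <- object@edges@edges
  cat("AtlasDB\n",
      " processes:   ", nrow(object@ontology@terms), "\n",
      " proteins:    ", nrow(object@proteins@proteins), "\n",
      " metabolites: ", nrow(object@metabolites@metabolites), "\n",
      " edges:       ", nrow(e),
      " (PPI ", sum(e$edge_type == "PPI"),
      ", PMI ", sum(e$edge_type == "PMI"),
      ", MMI ", sum(e$edge_type == "MMI"), ")\n", sep = "")
})

setMethod("show", "InteractionNetwork", function(object) {
  g <- object@graph
  kinds <- igraph::vertex_attr(g, "kind")
  cat("InteractionNetwork (", object@queryMode, " query, order ",
      object@order, ")\n",
      " nodes: ", igraph::vcount(g),
      " (", sum(kinds == "protein"), " proteins, ",
      sum(kinds == "metabolite"), " metabolites)\n",
      " edges: ", igraph::ecount(g), "\n", sep = "")
  if (length(object@isolatedProteins) > 0)
    cat(" isolated proteins:", length(object@isolatedProteins), "\n")
})
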