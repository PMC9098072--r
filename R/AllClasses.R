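#' @import methods
NULL

#' Immune-process ontology
#'
#' A rooted set of process terms (GO-style accessions) with parent links.
#' Only terms reachable from the root via parent links are retained by the
#' reader; the root itself has no parents.
#'
#' @slot terms data.frame with columns \code{term_id}, \code{name}.
#' @slot parents named list mapping each \code{term_id} to the character
#'   vector of its parent term ids (empty for the root).
#' @slot root the accession of the root term.
#'
#' @seealso [readGoTerms()], [processOntology()]
#' @exportClass ProcessOntology
setClass("ProcessOntology",
         representation(terms = "data.frame", parents = "list",
                        root = "character"))

setValidity("ProcessOntology", function(object) {
  msgs <- character(0)
  ids <- object@terms$term_id
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate term_id")
  if (length(object@root) != 1) msgs <- c(msgs, "root must be a single id")
  if (!setequal(names(object@parents), ids))
    msgs <- c(msgs, "parents list does not match term ids")
  if (length(msgs) == 0) TRUE else msgs
})

#' Protein catalog with immune-process annotations
#'
#' @slot proteins data.frame with columns \code{protein_id}, \code{name}.
#' @slot processes named list mapping each \code{protein_id} to the
#'   character vector of annotated process term ids (possibly empty).
#'
#' @seealso [readProteins()], [proteinCatalog()]
#' @exportClass ProteinCatalog
setClass("ProteinCatalog",
         representation(proteins = "data.frame", processes = "list"))

setValidity("ProteinCatalog", function(object) {
  ids <- object@proteins$protein_id
  if (anyDuplicated(ids)) return("duplicate protein_id")
  if (!setequal(names(object@processes), ids))
    return("process annotation list does not match protein ids")
  TRUE
})

#' Metabolite catalog
#'
#' Retained metabolites after the biological-role / inorganic filters, with
#' chemical taxonomy labels and raw protein links.
#'
#' @slot metabolites data.frame with columns \code{metabolite_id},
#'   \code{name}, \code{class}, \code{superclass}, \code{compound_id}.
#' @slot proteinLinks named list mapping each metabolite id to the character
#'   vector of linked protein ids (as given in the input, before the
#'   immune-protein filter applied by [buildPMI()]).
#'
#' @seealso [readMetabolites()], [metaboliteCatalog()]
#' @exportClass MetaboliteCatalog
setClass("MetaboliteCatalog",
         representation(metabolites = "data.frame", proteinLinks = "list"))

setValidity("MetaboliteCatalog", function(object) {
  ids <- object@metabolites$metabolite_id
  if (anyDuplicated(ids)) return("duplicate metabolite_id")
  if (!setequal(names(object@proteinLinks), ids))
    return("protein link list does not match metabolite ids")
  TRUE
})

#' Set of typed undirected edges
#'
#' Canonical (lexicographically ordered endpoints), deduplicated, without
#' self-loops. Edge types are \code{PPI} (protein-protein, with an integer
#' STRING-style confidence on the 0-1000 scale), \code{PMI}
#' (protein-metabolite) and \code{MMI} (metabolite-metabolite).
#'
#' @slot edges data.frame with columns \code{endpoint_a}, \code{endpoint_b},
#'   \code{edge_type}, \code{confidence} (integer, \code{NA} for non-PPI).
#'
#' @seealso [readPPI()], [buildPMI()], [expandReactions()], [edgeSet()]
#' @exportClass EdgeSet
setClass("EdgeSet", representation(edges = "data.frame"))

setValidity("EdgeSet", function(object) {
  e <- object@edges
  msgs <- character(0)
  need <- c("endpoint_a", "endpoint_b", "edge_type", "confidence")
  if (!all(need %in% names(e))) return("edge table missing required columns")
  if (nrow(e) > 0) {
    if (any(e$endpoint_a == e$endpoint_b)) msgs <- c(msgs, "self-loop present")
    if (any(e$endpoint_a > e$endpoint_b))
      msgs <- c(msgs, "edges not canonically ordered")
    key <- paste(e$endpoint_a, e$endpoint_b, e$edge_type, sep = "\r")
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edges")
    if (!all(e$edge_type %in% c("PPI", "PMI", "MMI")))
      msgs <- c(msgs, "unknown edge type")
    if (any(e$edge_type == "PPI" & is.na(e$confidence)))
      msgs <- c(msgs, "PPI edge without confidence")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Merged atlas of processes, proteins, metabolites and typed edges
#'
#' The background store on which query networks are built and against which
#' all statistics are computed. Holds the validated component catalogs, the
#' merged canonical edge set, an igraph representation for neighbour lookup,
#' and provenance row counts per input.
#'
#' @slot ontology a [ProcessOntology-class].
#' @slot proteins a [ProteinCatalog-class].
#' @slot metabolites a [MetaboliteCatalog-class].
#' @slot edges an [EdgeSet-class] containing all PPI, PMI and MMI edges.
#' @slot graph igraph object; vertices carry \code{kind}
#'   (\code{"protein"}/\code{"metabolite"}), \code{name} (the id),
#'   \code{label}, \code{superclass}.
#' @slot provenance data.frame with columns \code{source}, \code{rows}.
#'
#' @seealso [assembleAtlas()], [readAtlas()]
#' @exportClass AtlasDB
setClass("AtlasDB",
         representation(ontology = "ProcessOntology",
                        proteins = "ProteinCatalog",
                        metabolites = "MetaboliteCatalog",
                        edges = "EdgeSet",
                        graph = "ANY",
                        provenance = "data.frame"))

setValidity("AtlasDB", function(object) {
  msgs <- character(0)
  e <- object@edges@edges
  prot <- object@proteins@proteins$protein_id
  met <- object@metabolites@metabolites$metabolite_id
  nodes <- c(prot, met)
  if (nrow(e) > 0 &&
      !all(c(e$endpoint_a, e$endpoint_b) %in% nodes))
    msgs <- c(msgs, "dangling edge endpoint")
  pmi <- e[e$edge_type == "PMI", , drop = FALSE]
  if (nrow(pmi) > 0) {
    pmiProt <- intersect(unique(c(pmi$endpoint_a, pmi$endpoint_b)), prot)
    nproc <- lengths(object@proteins@processes[pmiProt])
    if (any(nproc == 0))
      msgs <- c(msgs, "PMI endpoint protein without immune-process annotation")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' Query-specific interaction network
#'
#' The subgraph induced by a process or metabolite query on an
#' [AtlasDB-class], on which centrality, precision and overrepresentation
#' statistics are computed.
#'
#' @slot graph igraph object restricted to the query's nodes; vertex and
#'   edge attributes as in [AtlasDB-class].
#' @slot queryMode \code{"by_process"} or \code{"by_metabolite"}.
#' @slot queryIds the ids that defined the query.
#' @slot order inheritance order associated with the query (1-3).
#' @slot isolatedProteins proteins retained in the network despite having
#'   zero edges (annotated to a queried process but unconnected).
#'
#' @seealso [buildProcessNetwork()], [buildMetaboliteNetwork()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
         representation(graph = "ANY", queryMode = "character",
                        queryIds = "character", order = "integer",
                        isolatedProteins = "character"))

setValidity("InteractionNetwork", function(object) {
  if (!object@queryMode %in% c("by_process", "by_metabolite"))
    return("queryMode must be by_process or by_metabolite")
  if (length(object@order) != 1 || !object@order %in% 1:3)
    return("order must be 1, 2 or 3")
  TRUE
})
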