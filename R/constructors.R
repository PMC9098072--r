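## User-facing constructors. The readers in ingest.R are thin wrappers that
## parse the TSV dialect and delegate here, so tests and scripts can also
## build atlases fully in memory.

#' Construct a ProcessOntology
#'
#' Restricts the supplied terms to the declared root and its descendants
#' (terms whose parent chain reaches the root). Unreachable terms are
#' dropped with a warning; a cycle among parent links is an error.
#'
#' @param terms data.frame with columns \code{term_id}, \code{name}.
#' @param parents named list mapping term ids to character vectors of
#'   parent term ids.
#' @param root root term accession, e.g. \code{"GO:0002376"}.
#' @param quiet suppress progress messages.
#' @return A [ProcessOntology-class].
#' @examples
#' processOntology(
#'   data.frame(term_id = c("GO:0002376", "GO:0002711"),
#'              name = c("immune system process",
#'                       "positive regulation of T cell mediated immunity")),
#'   parents = list("GO:0002376" = character(0),
#'                  "GO:0002711" = "GO:0002376"),
#'   root = "GO:0002376")
#' @export
processOntology <- function(terms, parents, root, quiet = FALSE) {
  terms <- data.frame(term_id = as.character(terms$term_id),
                      name = as.character(terms$name),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(terms$term_id))
    stop("validation error: duplicate term_id ",
         terms$term_id[duplicated(terms$term_id)][1], call. = FALSE)
  if (!root %in% terms$term_id)
    stop("root term ", root, " not present in term table", call. = FALSE)
  parents <- parents[terms$term_id]
  names(parents) <- terms$term_id
  parents <- lapply(parents, function(p) {
    if (is.null(p)) character(0) else as.character(p)
  })
  detectParentCycle(parents)
  ## Terms reachable from the root by following child -> parent links.
  reachable <- root
  repeat {
    more <- names(parents)[vapply(parents, function(p)
      any(p %in% reachable), logical(1))]
    more <- setdiff(more, reachable)
    if (length(more) == 0) break
    reachable <- c(reachable, more)
  }
  dropped <- setdiff(terms$term_id, reachable)
  if (length(dropped) > 0)
    imnMessage(length(dropped), " term(s) not reachable from root ", root,
               " dropped: ", paste(utils::head(dropped, 5), collapse = ", "),
               quiet = quiet)
  keep <- terms$term_id %in% reachable
  terms <- terms[keep, , drop = FALSE]
  rownames(terms) <- NULL
  parents <- parents[terms$term_id]
  ## Parent links to dropped terms are pruned; the root keeps none.
  parents <- lapply(parents, function(p) intersect(p, terms$term_id))
  parents[[root]] <- character(0)
  new("ProcessOntology", terms = terms, parents = parents, root = root)
}

## Kahn-style strip of terms whose parents are all resolved; leftovers are
## on a cycle.
detectParentCycle <- function(parents) {
  remaining <- names(parents)
  repeat {
    deg <- vapply(parents[remaining], function(p)
      sum(p %in% remaining), integer(1))
    free <- remaining[deg == 0]
    if (length(free) == 0) break
    remaining <- setdiff(remaining, free)
  }
  if (length(remaining) > 0)
    stop("validation error: parent-link cycle involving term ",
         sort(remaining)[1], call. = FALSE)
  invisible(NULL)
}

#' Construct a ProteinCatalog
#'
#' Annotations pointing at terms absent from the ontology are dropped per
#' protein (with a message); proteins may end up with empty process sets.
#'
#' @param proteins data.frame with columns \code{protein_id}, \code{name}.
#' @param processes named list mapping protein ids to character vectors of
#'   process term ids.
#' @param ontology a [ProcessOntology-class] used to resolve annotations.
#' @param quiet suppress progress messages.
#' @return A [ProteinCatalog-class].
#' @export
proteinCatalog <- function(proteins, processes, ontology, quiet = FALSE) {
  proteins <- data.frame(protein_id = as.character(proteins$protein_id),
                         name = as.character(proteins$name),
                         stringsAsFactors = FALSE)
  if (anyDuplicated(proteins$protein_id))
    stop("validation error: duplicate protein_id ",
         proteins$protein_id[duplicated(proteins$protein_id)][1],
         call. = FALSE)
  known <- ontology@terms$term_id
  processes <- processes[proteins$protein_id]
  names(processes) <- proteins$protein_id
  processes <- lapply(processes, function(p) {
    if (is.null(p)) character(0) else as.character(p)
  })
  nDropped <- sum(vapply(processes, function(p) sum(!p %in% known),
                         integer(1)))
  if (nDropped > 0)
    imnMessage(nDropped, " protein annotation(s) to unknown terms dropped",
               quiet = quiet)
  processes <- lapply(processes, function(p) sort(unique(intersect(p, known))))
  new("ProteinCatalog", proteins = proteins, processes = processes)
}

#' Construct a MetaboliteCatalog
#'
#' Applies the inclusion filters: rows must have a biological role and must
#' not be inorganic compounds; excluded rows are counted and reported.
#'
#' @param metabolites data.frame with columns \code{metabolite_id},
#'   \code{name}, \code{class}, \code{superclass}, \code{is_biological},
#'   \code{is_inorganic} (0/1), \code{compound_id}.
#' @param proteinLinks named list mapping metabolite ids to character
#'   vectors of linked protein ids.
#' @param quiet suppress progress messages.
#' @return A [MetaboliteCatalog-class] holding the retained rows.
#' @export
metaboliteCatalog <- function(metabolites, proteinLinks, quiet = FALSE) {
  ids <- as.character(metabolites$metabolite_id)
  if (anyDuplicated(ids))
    stop("validation error: duplicate metabolite_id ",
         ids[duplicated(ids)][1], call. = FALSE)
  bio <- as.integer(metabolites$is_biological) == 1L
  inorg <- as.integer(metabolites$is_inorganic) == 1L
  keep <- bio & !inorg
  nSynthetic <- sum(!bio)
  nInorganic <- sum(bio & inorg)
  if (any(!keep))
    imnMessage(sum(!keep), " metabolite(s) excluded (",
               nSynthetic, " without biological role, ",
               nInorganic, " inorganic)", quiet = quiet)
  df <- data.frame(metabolite_id = ids,
                   name = as.character(metabolites$name),
                   class = as.character(metabolites$class),
                   superclass = as.character(metabolites$superclass),
                   compound_id = as.character(metabolites$compound_id),
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(df) <- NULL
  proteinLinks <- proteinLinks[df$metabolite_id]
  names(proteinLinks) <- df$metabolite_id
  proteinLinks <- lapply(proteinLinks, function(p) {
    if (is.null(p)) character(0) else sort(unique(as.character(p)))
  })
  new("MetaboliteCatalog", metabolites = df, proteinLinks = proteinLinks)
}

#' Construct an EdgeSet from raw endpoint vectors
#'
#' Canonicalizes (lexicographic endpoint order), removes self-loops and
#' merges duplicates keeping the maximum confidence.
#'
#' @param endpoint_a,endpoint_b character vectors of node ids.
#' @param edge_type \code{"PPI"}, \code{"PMI"} or \code{"MMI"} (recycled).
#' @param confidence integer confidence scores (PPI) or \code{NA}.
#' @return An [EdgeSet-class].
#' @export
edgeSet <- function(endpoint_a = character(0), endpoint_b = character(0),
                    edge_type = character(0), confidence = NA_integer_) {
  df <- canonicalizeEdges(as.character(endpoint_a), as.character(endpoint_b),
                          edge_type, confidence)
  if (nrow(df) == 0) df <- emptyEdgeFrame()
  new("EdgeSet", edges = df)
}

mergeEdgeSets <- function(...) {
  dfs <- lapply(list(...), function(x) x@edges)
  df <- do.call(rbind, dfs)
  if (is.null(df) || nrow(df) == 0) return(new("EdgeSet", edges = emptyEdgeFrame()))
  edgeSet(df$endpoint_a, df$endpoint_b, df$edge_type, df$confidence)
}
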