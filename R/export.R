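## Standard-format export of networks and association tables.

#' Export an interaction network
#'
#' GraphML output carries node attributes \code{kind}, \code{label}
#' (display name) and \code{superclass} and edge attributes
#' \code{edge_type} and \code{confidence}, so metabolite/protein colouring
#' is reproducible downstream. The TSV edge list round-trips through
#' [readEdgeList()] to an equal edge set.
#'
#' @param network an [InteractionNetwork-class] (nonempty).
#' @param path output file path.
#' @param format \code{"graphml"} or \code{"tsv"}.
#' @return Invisibly, \code{path}.
#' @export
exportNetwork <- function(network, path, format = c("graphml", "tsv")) {
  format <- match.arg(format)
  g <- network@graph
  if (igraph::vcount(g) == 0)
    stop("cannot export an empty network", call. = FALSE)
  if (format == "graphml") {
    ## GraphML writers reject NA attribute values
    conf <- igraph::edge_attr(g, "confidence")
    if (!is.null(conf)) {
      conf[is.na(conf)] <- -1L
      g <- igraph::set_edge_attr(g, "confidence", value = conf)
    }
    sc <- igraph::vertex_attr(g, "superclass")
    if (!is.null(sc)) {
      sc[is.na(sc)] <- ""
      g <- igraph::set_vertex_attr(g, "superclass", value = sc)
    }
    lb <- igraph::vertex_attr(g, "label")
    if (!is.null(lb)) {
      lb[is.na(lb)] <- ""
      g <- igraph::set_vertex_attr(g, "label", value = lb)
    }
    igraph::write_graph(g, path, format = "graphml")
  } else {
    writeTsv(edgeTable(network), path)
  }
  invisible(path)
}

#' Read a TSV edge list back into an EdgeSet
#'
#' @param path TSV with columns \code{endpoint_a}, \code{endpoint_b},
#'   \code{edge_type}, \code{confidence}.
#' @return An [EdgeSet-class].
#' @export
readEdgeList <- function(path) {
  df <- readTsv(path, c("endpoint_a", "endpoint_b", "edge_type",
                        "confidence"))
  conf <- suppressWarnings(as.integer(df$confidence))
  edgeSet(df$endpoint_a, df$endpoint_b, df$edge_type, conf)
}

#' Write an association table
#'
#' Tab-separated, with floating-point columns at 6 significant digits so
#' repeated runs are byte-stable.
#'
#' @param table result of [rankAssociations()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeAssociationTable <- function(table, path) {
  cols <- c("metabolite_id", "process_id", "order_found", "centrality",
            "precision", "p", "q", "significant", "biomarker")
  cols <- intersect(cols, names(table))
  writeTsv(table[cols], path)
}

#' Export an inheritance result
#'
#' @param associations result of [inheritProcesses()].
#' @param path output TSV path; supporting proteins are pipe-joined.
#' @return Invisibly, \code{path}.
#' @export
writeAssociations <- function(associations, path) {
  df <- data.frame(metabolite_id = associations$metabolite_id,
                   process_id = associations$process_id,
                   order_found = associations$order_found,
                   supporting_protein_ids =
                     joinPipe(associations$supporting_proteins),
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
}
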