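## Query-network construction and order-k inheritance of immune processes.

newInteractionNetwork <- function(atlas, nodeIds, mode, queryIds, order = 1L) {
  g <- igraph::induced_subgraph(atlas@graph, nodeIds)
  kinds <- igraph::vertex_attr(g, "kind")
  deg <- igraph::degree(g)
  isolated <- sort(igraph::vertex_attr(g, "name")[kinds == "protein" & deg == 0])
  new("InteractionNetwork", graph = g, queryMode = mode,
      queryIds = sort(queryIds), order = as.integer(order),
      isolatedProteins = isolated)
}

#' Build the interaction network for immune processes of interest
#'
#' Nodes are the proteins annotated to any queried process plus the
#' metabolites PMI-linked to those proteins; edges are all atlas PPI edges
#' among the included proteins, all PMI edges between included proteins and
#' metabolites, and all MMI edges among the included metabolites. Proteins
#' annotated to a queried process but without any edge are retained and
#' flagged (see [isolatedProteins()]).
#'
#' @param atlas an [AtlasDB-class].
#' @param process_ids character vector of process term ids.
#' @param order inheritance order recorded on the network (1-3).
#' @return An [InteractionNetwork-class].
#' @export
buildProcessNetwork <- function(atlas, process_ids, order = 1L) {
  process_ids <- as.character(process_ids)
  unknown <- setdiff(process_ids, immuneProcesses(atlas))
  if (length(unknown) > 0)
    stop("lookup error: unknown process id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ann <- atlas@proteins@processes
  prots <- names(ann)[vapply(ann, function(p) any(p %in% process_ids),
                             logical(1))]
  e <- atlas@edges@edges
  pmi <- e[e$edge_type == "PMI", , drop = FALSE]
  inA <- pmi$endpoint_a %in% prots
  inB <- pmi$endpoint_b %in% prots
  partners <- c(pmi$endpoint_b[inA], pmi$endpoint_a[inB])
  mets <- intersect(unique(partners),
                    atlas@metabolites@metabolites$metabolite_id)
  newInteractionNetwork(atlas, c(sort(prots), sort(mets)),
                        "by_process", process_ids, order)
}

#' Build the interaction network around metabolites of interest
#'
#' Nodes are the query metabolites plus their PMI protein partners; for
#' \code{order} above 1 the protein set is expanded along protein-protein
#' edges by up to \code{order - 1} hops, so that second- and third-order
#' inheritance can reach the indirect neighbours. Edges are as in
#' [buildProcessNetwork()] restricted to these nodes. A query metabolite
#' without any PMI link yields a single-node component and a warning,
#' because at least one protein-metabolite interaction is needed to
#' inherit immune processes.
#'
#' @param atlas an [AtlasDB-class].
#' @param metabolite_ids character vector of metabolite ids (post-filter).
#' @param order inheritance order the network is built for (1-3).
#' @return An [InteractionNetwork-class].
#' @export
buildMetaboliteNetwork <- function(atlas, metabolite_ids, order = 1L) {
  metabolite_ids <- as.character(metabolite_ids)
  known <- atlas@metabolites@metabolites$metabolite_id
  unknown <- setdiff(metabolite_ids, known)
  if (length(unknown) > 0)
    stop("lookup error: unknown metabolite id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  e <- atlas@edges@edges
  pmi <- e[e$edge_type == "PMI", , drop = FALSE]
  inA <- pmi$endpoint_a %in% metabolite_ids
  inB <- pmi$endpoint_b %in% metabolite_ids
  prots <- unique(c(pmi$endpoint_b[inA], pmi$endpoint_a[inB]))
  prots <- intersect(prots, atlas@proteins@proteins$protein_id)
  if (order > 1 && length(prots) > 0) {
    ppi <- e[e$edge_type == "PPI", , drop = FALSE]
    frontier <- prots
    for (d in seq_len(order - 1)) {
      hitA <- ppi$endpoint_a %in% frontier
      hitB <- ppi$endpoint_b %in% frontier
      frontier <- setdiff(unique(c(ppi$endpoint_b[hitA],
                                   ppi$endpoint_a[hitB])), prots)
      if (length(frontier) == 0) break
      prots <- c(prots, frontier)
    }
  }
  linked <- intersect(unique(c(pmi$endpoint_a[inA], pmi$endpoint_b[inB])),
                      metabolite_ids)
  noLink <- setdiff(metabolite_ids, linked)
  if (length(noLink) > 0)
    warning("metabolite(s) without protein-metabolite interactions cannot ",
            "inherit immune processes: ", paste(noLink, collapse = ", "),
            call. = FALSE)
  newInteractionNetwork(atlas, c(sort(prots), sort(metabolite_ids)),
                        "by_metabolite", metabolite_ids, order)
}

## Adjacency lists by edge type from an igraph object of this package.
typedAdjacency <- function(g) {
  df <- graphEdgeFrame(g)
  adj <- list(PMI = list(), PPI = list())
  for (tp in c("PMI", "PPI")) {
    sub <- df[df$edge_type == tp, , drop = FALSE]
    if (nrow(sub) == 0) next
    both <- data.frame(a = c(sub$endpoint_a, sub$endpoint_b),
                       b = c(sub$endpoint_b, sub$endpoint_a),
                       stringsAsFactors = FALSE)
    adj[[tp]] <- split(both$b, both$a)
  }
  adj
}

#' Inherit immune processes onto metabolites
#'
#' For each metabolite, collects the immune processes of every protein
#' reachable by one protein-metabolite edge followed by at most
#' \code{order - 1} protein-protein edges. Metabolite-metabolite edges
#' never transmit processes. The contributing proteins are listed per
#' association, and \code{order_found} is the minimal qualifying depth
#' (1 = direct neighbour).
#'
#' @param atlas an [AtlasDB-class] (source of protein annotations).
#' @param network an [InteractionNetwork-class]; required for
#'   \code{scope = "network"}.
#' @param order inheritance order, 1, 2 or 3.
#' @param scope \code{"network"} traverses only edges present in the built
#'   network (the default query semantics); \code{"atlas"} traverses the
#'   full atlas graph (used for database-side counts and gold-standard
#'   evaluation).
#' @param metabolites optional explicit metabolite set; defaults to the
#'   network's metabolites (network scope) or all atlas metabolites with a
#'   PMI edge (atlas scope).
#' @return data.frame with columns \code{metabolite_id},
#'   \code{process_id}, \code{order_found} and list-column
#'   \code{supporting_proteins}, sorted by metabolite then process id.
#' @export
inheritProcesses <- function(atlas, network = NULL, order = 1L,
                             scope = c("network", "atlas"),
                             metabolites = NULL) {
  scope <- match.arg(scope)
  if (length(order) != 1 || !order %in% 1:3)
    stop("parameter error: order must be 1, 2 or 3", call. = FALSE)
  order <- as.integer(order)
  if (scope == "network") {
    if (is.null(network))
      stop("network scope requires a built network", call. = FALSE)
    g <- network@graph
    if (is.null(metabolites))
      metabolites <- networkNodes(network, "metabolite")
  } else {
    g <- atlas@graph
    if (is.null(metabolites)) {
      e <- atlas@edges@edges
      pmi <- e[e$edge_type == "PMI", , drop = FALSE]
      metabolites <- intersect(atlas@metabolites@metabolites$metabolite_id,
                               unique(c(pmi$endpoint_a, pmi$endpoint_b)))
    }
  }
  adj <- typedAdjacency(g)
  ann <- atlas@proteins@processes
  rows <- vector("list", length(metabolites))
  metabolites <- sort(metabolites)
  for (i in seq_along(metabolites)) {
    m <- metabolites[i]
    depth <- proteinDepths(m, adj, order)
    if (length(depth) == 0) next
    prots <- names(depth)
    procPer <- ann[prots]
    procAll <- unlist(procPer, use.names = FALSE)
    if (length(procAll) == 0) next
    protRep <- rep(prots, lengths(procPer))
    depthRep <- rep(unname(depth), lengths(procPer))
    byProc <- split(seq_along(procAll), procAll)
    procIds <- names(byProc)
    rows[[i]] <- data.frame(
      metabolite_id = m,
      process_id = procIds,
      order_found = vapply(byProc, function(ix) min(depthRep[ix]), numeric(1)),
      stringsAsFactors = FALSE)
    rows[[i]]$supporting_proteins <-
      lapply(byProc, function(ix) sort(unique(protRep[ix])))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(metabolite_id = character(0), process_id = character(0),
                      order_found = numeric(0), stringsAsFactors = FALSE)
    out$supporting_proteins <- list()
    return(out)
  }
  out <- out[base::order(out$metabolite_id, out$process_id), , drop = FALSE]
  out$order_found <- as.integer(out$order_found)
  rownames(out) <- NULL
  out
}

## Minimal depth (1 = PMI neighbour, +1 per PPI hop) of each protein
## reachable from metabolite m within the allowed order.
proteinDepths <- function(m, adj, order) {
  frontier <- adj$PMI[[m]]
  if (is.null(frontier) || length(frontier) == 0) return(integer(0))
  frontier <- unique(frontier)
  depth <- stats::setNames(rep(1L, length(frontier)), frontier)
  d <- 1L
  while (d < order && length(frontier) > 0) {
    nxt <- unique(unlist(adj$PPI[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(depth))
    if (length(nxt) > 0)
      depth[nxt] <- d + 1L
    frontier <- nxt
    d <- d + 1L
  }
  depth
}

#' Association pairs as a two-column data.frame
#'
#' Convenience to reduce an inheritance result to its unique
#' (metabolite, process) pairs.
#'
#' @param associations result of [inheritProcesses()] or
#'   [rankAssociations()].
#' @return data.frame with columns \code{metabolite_id}, \code{process_id}.
#' @export
associationPairs <- function(associations) {
  df <- unique(data.frame(metabolite_id = associations$metabolite_id,
                          process_id = associations$process_id,
                          stringsAsFactors = FALSE))
  df <- df[order(df$metabolite_id, df$process_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}
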