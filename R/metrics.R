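## Association scoring: harmonic closeness, precision, Fisher
## overrepresentation with BH-FDR, ranking and biomarker selection.

#' Harmonic closeness centrality
#'
#' For node i, the raw score is the sum over all other nodes j of the
#' reciprocal shortest-path hop distance 1/d(i,j), with unreachable nodes
#' contributing 0 — well-defined on disconnected graphs. The normalized
#' score divides by (n - 1), the maximum attainable, mapping onto [0, 1];
#' a singleton network scores 0.
#'
#' @param network an [InteractionNetwork-class].
#' @param nodes node ids to score; defaults to all metabolites in the
#'   network.
#' @return data.frame with columns \code{node_id}, \code{raw},
#'   \code{normalized}.
#' @export
harmonicCloseness <- function(network, nodes = NULL) {
  g <- network@graph
  if (is.null(nodes)) nodes <- networkNodes(network, "metabolite")
  nodes <- as.character(nodes)
  all <- igraph::vertex_attr(g, "name")
  unknown <- setdiff(nodes, all)
  if (length(unknown) > 0)
    stop("node(s) not in network: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- igraph::vcount(g)
  if (length(nodes) == 0)
    return(data.frame(node_id = character(0), raw = numeric(0),
                      normalized = numeric(0)))
  raw <- igraph::harmonic_centrality(g, vids = nodes, normalized = FALSE)
  norm <- if (n > 1) raw / (n - 1) else rep(0, length(raw))
  data.frame(node_id = nodes, raw = unname(raw), normalized = unname(norm),
             stringsAsFactors = FALSE)
}

#' Precision score of a metabolite for a process
#'
#' The ratio mode (default) is N_ij / N_i: the fraction of metabolite i's
#' interacting nodes in the whole atlas that lie inside the process-j
#' network — 1.0 for a metabolite fully committed to the process. The
#' corrected mode additionally divides by V_j, the node count of the
#' process network.
#'
#' @param n_ij count of metabolite i's interacting nodes within the
#'   process-j network.
#' @param n_i count of metabolite i's interacting nodes in the whole atlas.
#' @param v_j node count of the process-j network (corrected mode only).
#' @param mode \code{"ratio"} or \code{"corrected"}.
#' @return Numeric score; \code{NA} when \code{n_i} is 0 (a metabolite
#'   without interactions cannot be scored).
#' @export
precisionScore <- function(n_ij, n_i, v_j = NULL,
                           mode = c("ratio", "corrected")) {
  mode <- match.arg(mode)
  if (any(n_ij > n_i, na.rm = TRUE))
    stop("invalid precision inputs: n_ij exceeds n_i", call. = FALSE)
  out <- ifelse(n_i > 0, n_ij / n_i, NA_real_)
  if (mode == "corrected") {
    if (is.null(v_j))
      stop("corrected mode requires v_j", call. = FALSE)
    if (any(v_j < 1, na.rm = TRUE))
      stop("invalid precision inputs: v_j must be >= 1", call. = FALSE)
    out <- out / v_j
  }
  out
}

#' Fisher's exact test p-value for a 2x2 contingency table
#'
#' Computed from hypergeometric point probabilities at fixed margins, in
#' log space for overflow safety. The default one-sided (greater)
#' alternative sums tables at least as extreme toward enrichment of cell
#' \code{a}; the two-sided alternative sums all point probabilities not
#' exceeding the observed one.
#'
#' @param a,b,c,d nonnegative cell counts, or \code{a} may be a 2x2 matrix
#'   or a length-4 vector (a, b, c, d).
#' @param sided \code{"one_sided_greater"} or \code{"two_sided"}.
#' @return The p-value. An all-zero table yields 1 with a warning.
#' @examples
#' fisherP(5, 0, 0, 5)              # 1 / choose(10, 5)
#' fisherP(0, 5, 5, 0)              # 1: least enriched table
#' @importFrom stats dhyper phyper
#' @export
fisherP <- function(a, b = NULL, c = NULL, d = NULL,
                    sided = c("one_sided_greater", "two_sided")) {
  sided <- match.arg(sided)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  } else if (length(a) == 4 && is.null(b)) {
    b <- a[[2]]; c <- a[[3]]; d <- a[[4]]; a <- a[[1]]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells))
    stop("contingency cells must be nonnegative counts", call. = FALSE)
  if (all(cells == 0)) {
    warning("all-zero contingency table; p = 1", call. = FALSE)
    return(1)
  }
  m <- a + b; n <- c + d; k <- a + c
  if (sided == "one_sided_greater")
    return(stats::phyper(a - 1, m, n, k, lower.tail = FALSE))
  ## two-sided: sum point probabilities <= observed (with relative slack
  ## against floating-point ties, as in stats::fisher.test)
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-07)]))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment pooled over all tested metabolite-process pairs of a
#' network run; adjusted values are monotone and never below the raw
#' p-values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of q-values of the same length.
#' @importFrom stats p.adjust
#' @export
adjustFdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

## Named list node -> all atlas neighbours (any edge type).
atlasAdjacency <- function(atlas) {
  df <- atlas@edges@edges
  if (nrow(df) == 0) return(list())
  both <- data.frame(a = c(df$endpoint_a, df$endpoint_b),
                     b = c(df$endpoint_b, df$endpoint_a),
                     stringsAsFactors = FALSE)
  lapply(split(both$b, both$a), unique)
}

#' Contingency table for metabolite-based overrepresentation
#'
#' Tests whether the metabolite's database neighbourhood is enriched inside
#' the process network relative to the rest of the atlas. With D the atlas
#' node count, V' the process-network node count (excluding the metabolite
#' itself), N_i the metabolite's atlas neighbours and N_ij those inside the
#' network: \code{a = N_ij}, \code{b = V' - N_ij} (network nodes not
#' interacting with the metabolite), \code{c = N_i - N_ij} (the
#' database-minus-network complement of its associations) and
#' \code{d = (D - 1 - V') - c}. When the network is the whole atlas the
#' complements vanish (c = d = 0) and p = 1.
#'
#' @param atlas an [AtlasDB-class].
#' @param network the [InteractionNetwork-class] of the process of
#'   interest.
#' @param metabolite_id metabolite to test.
#' @param process_id process of interest (recorded; the network defines the
#'   scope).
#' @return Named numeric vector with elements a, b, c, d.
#' @export
metaboliteContingency <- function(atlas, network, metabolite_id,
                                  process_id = NULL) {
  adj <- atlasAdjacency(atlas)
  nodes <- igraph::vertex_attr(network@graph, "name")
  D <- igraph::vcount(atlas@graph)
  contingencyFromCounts(adj, nodes, D, metabolite_id)
}

contingencyFromCounts <- function(adj, networkNodes, D, metabolite_id) {
  nb <- adj[[metabolite_id]]
  if (is.null(nb)) nb <- character(0)
  others <- setdiff(networkNodes, metabolite_id)
  nij <- sum(nb %in% others)
  ni <- length(nb)
  vprime <- length(others)
  a <- nij
  b <- vprime - nij
  c <- ni - nij
  d <- (D - 1 - vprime) - c
  if (b < 0 || c < 0 || d < 0)
    stop("internal-consistency error: network counts exceed database counts",
         call. = FALSE)
  c(a = a, b = b, c = c, d = d)
}

#' Contingency table for process-based overrepresentation
#'
#' Literal network-versus-database appearance counts: \code{a} is the
#' number of annotation instances of the process among the network's
#' proteins, \code{b} the same count over the whole atlas, \code{c} the
#' annotation instances of all other processes in the network and \code{d}
#' those in the atlas. When the network equals the whole atlas, a = b and
#' c = d, and the two-sided p-value is 1.
#'
#' @param atlas an [AtlasDB-class].
#' @param network an [InteractionNetwork-class].
#' @param process_id process term to test.
#' @return Named numeric vector with elements a, b, c, d.
#' @export
processContingency <- function(atlas, network, process_id) {
  ann <- atlas@proteins@processes
  netProt <- networkNodes(network, "protein")
  netAnn <- unlist(ann[netProt], use.names = FALSE)
  allAnn <- unlist(ann, use.names = FALSE)
  a <- sum(netAnn == process_id)
  b <- sum(allAnn == process_id)
  if (b == 0)
    stop("process ", process_id, " has no annotations anywhere; ",
         "untestable table", call. = FALSE)
  c <- sum(netAnn != process_id)
  d <- sum(allAnn != process_id)
  c(a = a, b = b, c = c, d = d)
}

#' Score and rank metabolite-process associations
#'
#' Runs inheritance on the network, then scores every inherited
#' (metabolite, process) pair: normalized harmonic closeness of the
#' metabolite in the query network, precision against the pair's process
#' network derived from the atlas, Fisher overrepresentation p-value and
#' pooled BH-FDR q-value. Rows are sorted by q ascending with ties broken
#' by precision, then centrality (both descending), then ids.
#'
#' @param atlas an [AtlasDB-class].
#' @param network an [InteractionNetwork-class].
#' @param order inheritance order (1-3).
#' @param sided sidedness of the Fisher test, see [fisherP()].
#' @param precision_mode \code{"ratio"} (default) or \code{"corrected"},
#'   see [precisionScore()].
#' @param alpha significance threshold on the q-value (default 0.05).
#' @param sd_multiplier biomarker threshold multiplier (default 2: mean
#'   plus two standard deviations).
#' @param flag_biomarkers compute the biomarker flag column (default TRUE).
#' @return data.frame with columns \code{metabolite_id},
#'   \code{process_id}, \code{order_found}, \code{centrality},
#'   \code{precision}, \code{p}, \code{q}, \code{significant},
#'   \code{biomarker}.
#' @export
rankAssociations <- function(atlas, network, order = 1L,
                             sided = c("one_sided_greater", "two_sided"),
                             precision_mode = c("ratio", "corrected"),
                             alpha = 0.05, sd_multiplier = 2,
                             flag_biomarkers = TRUE) {
  sided <- match.arg(sided)
  precision_mode <- match.arg(precision_mode)
  assoc <- inheritProcesses(atlas, network, order = order, scope = "network")
  if (nrow(assoc) == 0) {
    out <- data.frame(metabolite_id = character(0), process_id = character(0),
                      order_found = integer(0), centrality = numeric(0),
                      precision = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), biomarker = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  cent <- harmonicCloseness(network)
  centLookup <- stats::setNames(cent$normalized, cent$node_id)
  adj <- atlasAdjacency(atlas)
  D <- igraph::vcount(atlas@graph)
  procNets <- lapply(
    stats::setNames(nm = unique(assoc$process_id)),
    function(j) networkNodes(buildProcessNetwork(atlas, j), "all"))
  n <- nrow(assoc)
  precision <- numeric(n)
  p <- numeric(n)
  for (i in seq_len(n)) {
    m <- assoc$metabolite_id[i]
    nodes <- procNets[[assoc$process_id[i]]]
    tab <- contingencyFromCounts(adj, nodes, D, m)
    nij <- unname(tab["a"])
    ni <- nij + unname(tab["c"])
    precision[i] <- precisionScore(nij, ni, v_j = length(nodes),
                                   mode = precision_mode)
    p[i] <- fisherP(tab, sided = sided)
  }
  out <- data.frame(metabolite_id = assoc$metabolite_id,
                    process_id = assoc$process_id,
                    order_found = assoc$order_found,
                    centrality = unname(centLookup[assoc$metabolite_id]),
                    precision = precision, p = p, q = adjustFdr(p),
                    stringsAsFactors = FALSE)
  out$significant <- out$q < alpha
  out <- out[base::order(out$q, -out$precision, -out$centrality,
                         out$metabolite_id, out$process_id), , drop = FALSE]
  rownames(out) <- NULL
  out$biomarker <- if (flag_biomarkers)
    biomarkerFlags(out, sd_multiplier = sd_multiplier) else FALSE
  out
}

## Logical flag per row: significant AND both scores strictly above
## mean + sd_multiplier * sample SD of the significant subset.
biomarkerFlags <- function(table, sd_multiplier = 2) {
  flags <- rep(FALSE, nrow(table))
  sig <- which(table$significant)
  if (length(sig) == 0) return(flags)
  if (length(sig) < 2) {
    warning("fewer than 2 significant associations; biomarker threshold ",
            "undefined, no rows flagged", call. = FALSE)
    return(flags)
  }
  cc <- table$centrality[sig]
  pp <- table$precision[sig]
  thrC <- mean(cc) + sd_multiplier * stats::sd(cc)
  thrP <- mean(pp) + sd_multiplier * stats::sd(pp)
  flags[sig] <- table$centrality[sig] > thrC & table$precision[sig] > thrP
  flags
}

#' Select biomarker candidates from an association table
#'
#' Restricts to statistically significant rows, computes the mean and
#' sample standard deviation of centrality and precision over that subset,
#' and returns the rows strictly exceeding mean + \code{sd_multiplier} x SD
#' on both dimensions. With fewer than two significant rows the threshold
#' is undefined and no rows are returned (with a warning).
#'
#' @param table result of [rankAssociations()].
#' @param sd_multiplier threshold multiplier (default 2).
#' @return The flagged subset of \code{table}, with \code{biomarker} set.
#' @export
selectBiomarkers <- function(table, sd_multiplier = 2) {
  flags <- biomarkerFlags(table, sd_multiplier = sd_multiplier)
  out <- table[flags, , drop = FALSE]
  if (nrow(out) > 0) out$biomarker <- TRUE
  rownames(out) <- NULL
  out
}

#' Metabolite superclass distribution over process groups
#'
#' Counts unique metabolites per (group, superclass) cell, where groups are
#' supplied as a user mapping from process ids to high-level labels (for
#' example a textbook categorization of immune responses). Processes
#' without a mapping fall into group \code{"other"}; superclasses in
#' \code{exclude_superclasses} (typically lipids and lipid-like molecules)
#' are removed before counting.
#'
#' @param table result of [rankAssociations()] (or any data.frame with
#'   \code{metabolite_id} and \code{process_id}).
#' @param atlas an [AtlasDB-class] providing metabolite superclasses.
#' @param group_map named character vector mapping process ids to group
#'   labels.
#' @param exclude_superclasses character vector of superclasses to drop.
#' @return data.frame with columns \code{group}, \code{superclass},
#'   \code{n_metabolites}.
#' @export
summarizeSuperclasses <- function(table, atlas, group_map = character(0),
                                  exclude_superclasses = character(0)) {
  mt <- metaboliteTable(atlas)
  sclass <- stats::setNames(mt$superclass, mt$metabolite_id)
  df <- data.frame(metabolite_id = table$metabolite_id,
                   process_id = table$process_id,
                   stringsAsFactors = FALSE)
  df$superclass <- unname(sclass[df$metabolite_id])
  df <- df[!df$superclass %in% exclude_superclasses, , drop = FALSE]
  grp <- unname(group_map[df$process_id])
  grp[is.na(grp)] <- "other"
  df$group <- grp
  df <- unique(df[c("metabolite_id", "group", "superclass")])
  if (nrow(df) == 0)
    return(data.frame(group = character(0), superclass = character(0),
                      n_metabolites = integer(0), stringsAsFactors = FALSE))
  agg <- stats::aggregate(metabolite_id ~ group + superclass, data = df,
                          FUN = function(x) length(unique(x)))
  names(agg)[names(agg) == "metabolite_id"] <- "n_metabolites"
  agg <- agg[base::order(agg$group, agg$superclass), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
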