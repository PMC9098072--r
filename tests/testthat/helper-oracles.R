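## Independent brute-force oracles. These deliberately avoid the package's
## own code paths (igraph centrality, dhyper/phyper, BFS helpers).

## Adjacency list (named list of character vectors) from an undirected
## edge data.frame with columns endpoint_a/endpoint_b.
oracleAdjacency <- function(edges, nodes) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  adj[] <- list(character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$endpoint_a[i]; b <- edges$endpoint_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

## Plain queue BFS hop distances from one start node; unreachable = Inf.
oracleBfs <- function(adj, start) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[start] <- 0
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

## Harmonic closeness by exhaustive BFS: sum of reciprocal distances.
oracleHarmonic <- function(edges, nodes, node) {
  adj <- oracleAdjacency(edges, nodes)
  d <- oracleBfs(adj, node)
  d <- d[names(d) != node]
  sum(1 / d[is.finite(d) & d > 0])
}

## Exact Fisher p by enumeration of all tables at fixed margins, with
## point probabilities from choose() (exact in doubles for margins <= 12).
oracleFisher <- function(a, b, c, d, sided = "one_sided_greater") {
  m <- a + b; n <- c + d; k <- a + c
  supp <- max(0, k - n):min(k, m)
  pt <- choose(m, supp) * choose(n, k - supp) / choose(m + n, k)
  if (sided == "one_sided_greater") {
    sum(pt[supp >= a])
  } else {
    obs <- choose(m, a) * choose(n, c) / choose(m + n, k)
    min(1, sum(pt[pt <= obs * (1 + 1e-07)]))
  }
}

## Order-k inheritance by boolean matrix reachability: one PMI hop then
## up to k-1 PPI hops. Returns data.frame(metabolite_id, process_id,
## order_found) over all metabolites with any PMI link.
oracleInherit <- function(atlas, order) {
  e <- edgeTable(atlas)
  prot <- proteinTable(atlas)$protein_id
  met <- metaboliteTable(atlas)$metabolite_id
  A <- matrix(0L, length(prot), length(prot), dimnames = list(prot, prot))
  ppi <- e[e$edge_type == "PPI", , drop = FALSE]
  for (i in seq_len(nrow(ppi))) {
    A[ppi$endpoint_a[i], ppi$endpoint_b[i]] <- 1L
    A[ppi$endpoint_b[i], ppi$endpoint_a[i]] <- 1L
  }
  M <- matrix(0L, length(met), length(prot), dimnames = list(met, prot))
  pmi <- e[e$edge_type == "PMI", , drop = FALSE]
  for (i in seq_len(nrow(pmi))) {
    mm <- intersect(c(pmi$endpoint_a[i], pmi$endpoint_b[i]), met)
    pp <- intersect(c(pmi$endpoint_a[i], pmi$endpoint_b[i]), prot)
    M[mm, pp] <- 1L
  }
  ann <- processAnnotations(atlas)
  ## minimal depth = first k with M (I + A)^(k-1) > 0
  depth <- ifelse(M > 0, 1L, NA_integer_)
  reach <- M
  if (order > 1 && length(prot) > 0) {
    IplusA <- diag(length(prot)) + A
    for (k in 2:order) {
      reach <- (reach %*% IplusA > 0) * 1L
      newly <- reach > 0 & is.na(depth)
      depth[newly] <- k
    }
  }
  rows <- list()
  for (m in met) {
    prots <- prot[!is.na(depth[m, ])]
    if (length(prots) == 0) next
    procs <- unique(unlist(ann[prots], use.names = FALSE))
    for (pr in procs) {
      carriers <- prots[vapply(ann[prots], function(x) pr %in% x, logical(1))]
      rows[[length(rows) + 1]] <- data.frame(
        metabolite_id = m, process_id = pr,
        order_found = min(depth[m, carriers]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(metabolite_id = character(0),
                      process_id = character(0),
                      order_found = integer(0)))
  rownames(out) <- NULL
  out[order(out$metabolite_id, out$process_id), , drop = FALSE]
}
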