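test_that("harmonic closeness matches hand values on paths and disconnected dyads", {
  gPath <- igraph::make_graph(~ A - B, B - C)
  net <- wrapNetwork(gPath)
  sc <- harmonicCloseness(net, nodes = c("A", "B", "C"))
  expect_equal(sc$raw, c(1.5, 2.0, 1.5))
  expect_equal(sc$normalized, c(0.75, 1.0, 0.75))

  gDyads <- igraph::make_graph(~ A - B, C - D)
  sc2 <- harmonicCloseness(wrapNetwork(gDyads), nodes = c("A", "B", "C", "D"))
  expect_equal(sc2$raw, rep(1, 4))
  expect_equal(sc2$normalized, rep(1 / 3, 4))

  ## singleton network: defined, zero
  g1 <- igraph::make_empty_graph(n = 1, directed = FALSE)
  sc3 <- harmonicCloseness(wrapNetwork(g1), nodes = "N1")
  expect_equal(sc3$raw, 0)
  expect_equal(sc3$normalized, 0)

  expect_error(harmonicCloseness(net, nodes = "Z"), "not in network")
})

test_that("harmonic closeness equals BFS brute force on random graphs", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(4:30, 1)
    g <- igraph::sample_gnp(n, stats::runif(1, 0.03, 0.3), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = sprintf("V%02d", 1:n))
    net <- wrapNetwork(g)
    nodes <- sprintf("V%02d", 1:n)
    got <- harmonicCloseness(net, nodes = nodes)
    e <- graphEdges(g)
    want <- vapply(nodes, function(v) oracleHarmonic(e, nodes, v), numeric(1))
    expect_equal(got$raw, unname(want), tolerance = 1e-12)
    expect_true(all(got$normalized >= 0 & got$normalized <= 1))
  }
})

test_that("nodes with identical neighbour sets receive equal centrality", {
  atlas <- toyAtlas()
  net <- buildProcessNetwork(atlas, "GO:0002711")
  sc <- harmonicCloseness(net, nodes = paste0("MB0", 1:5))
  expect_length(unique(sc$normalized), 1L)
})

test_that("precision score arithmetic and degenerate inputs behave as defined", {
  expect_equal(precisionScore(2, 4), 0.5)
  expect_equal(precisionScore(2, 4, v_j = 10, mode = "corrected"), 0.05)
  expect_equal(precisionScore(0, 4), 0)
  expect_true(is.na(precisionScore(0, 0)))
  expect_error(precisionScore(5, 4), "exceeds")
  expect_error(precisionScore(1, 2, mode = "corrected"), "requires v_j")
  ## corrected never exceeds the ratio when the network is nonempty
  for (v in 1:5)
    expect_lte(precisionScore(3, 7, v_j = v, mode = "corrected"),
               precisionScore(3, 7))
})

test_that("Fisher p-values match hand-derived extreme tables", {
  expect_equal(fisherP(5, 0, 0, 5), 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(fisherP(0, 5, 5, 0), 1)
  expect_equal(fisherP(0, 13, 0, 4), 1)
  expect_warning(p <- fisherP(0, 0, 0, 0), "all-zero")
  expect_equal(p, 1)
  expect_error(fisherP(-1, 2, 3, 4), "nonnegative")
  ## matrix and vector forms agree
  expect_equal(fisherP(matrix(c(3, 1, 2, 4), 2, byrow = TRUE)),
               fisherP(c(3, 1, 2, 4)))
})

test_that("Fisher p-values match enumeration and stats::fisher.test", {
  for (tab in list(c(3, 1, 2, 4), c(6, 2, 1, 7), c(0, 4, 4, 0),
                   c(2, 2, 2, 2), c(8, 0, 3, 5), c(1, 9, 7, 3))) {
    m <- matrix(tab, 2, byrow = TRUE)
    expect_equal(fisherP(tab, sided = "one_sided_greater"),
                 oracleFisher(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
    expect_equal(fisherP(tab, sided = "one_sided_greater"),
                 stats::fisher.test(m, alternative = "greater")$p.value,
                 tolerance = 1e-09)
    expect_equal(fisherP(tab, sided = "two_sided"),
                 stats::fisher.test(m)$p.value, tolerance = 1e-09)
  }
})

test_that("two-sided Fisher p is symmetric to transposing the groups", {
  for (tab in list(c(3, 1, 2, 4), c(5, 2, 7, 1), c(0, 3, 6, 2))) {
    expect_equal(fisherP(tab, sided = "two_sided"),
                 fisherP(c(tab[1], tab[3], tab[2], tab[4]),
                         sided = "two_sided"),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjustFdr(0.2), 0.2)
  expect_identical(adjustFdr(numeric(0)), numeric(0))
  expect_error(adjustFdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  p <- stats::runif(50)
  q <- adjustFdr(p)
  expect_true(all(q >= p))
  ## monotone: ordering by p never reverses the ordering of q
  expect_true(all(diff(q[base::order(p)]) >= -1e-15))
})

test_that("metabolite contingency matches hand enumeration on the packaged toy", {
  atlas <- toyAtlas()
  net <- buildProcessNetwork(atlas, "GO:0002711")
  ## atlas: 18 nodes; network: 14; MB05 neighbours PR01-PR03, all inside
  tab <- metaboliteContingency(atlas, net, "MB05", "GO:0002711")
  expect_equal(unname(tab), c(3, 10, 0, 4))
  ## MB01 additionally touches PR07 outside the network
  tab2 <- metaboliteContingency(atlas, net, "MB01", "GO:0002711")
  expect_equal(unname(tab2), c(3, 10, 1, 3))
  ## a metabolite absent from the process in both scopes: a = 0, p = 1
  tab3 <- metaboliteContingency(atlas, net, "MB09", "GO:0002711")
  expect_equal(unname(tab3["a"]), 0)
  expect_equal(fisherP(tab3), 1)
})

test_that("complements vanish when the network is the whole atlas", {
  atlas <- makeAtlas(list("GO:R" = character(0), "GO:A" = "GO:R"),
                     annotations = list(P1 = "GO:A", P2 = "GO:A"),
                     metaboliteLinks = list(M1 = "P1", M2 = "P2"),
                     ppi = data.frame(a = "P1", b = "P2", s = 700L))
  net <- buildProcessNetwork(atlas, "GO:A")
  expect_length(networkNodes(net), 4L)   # the entire atlas
  for (m in c("M1", "M2")) {
    tab <- metaboliteContingency(atlas, net, m, "GO:A")
    expect_equal(unname(tab["c"]), 0)
    expect_equal(unname(tab["d"]), 0)
    expect_equal(fisherP(tab), 1)
  }
  ## process-based: a = b and c = d, two-sided p = 1
  ptab <- processContingency(atlas, net, "GO:A")
  expect_equal(unname(ptab["a"]), unname(ptab["b"]))
  expect_equal(unname(ptab["c"]), unname(ptab["d"]))
  expect_equal(fisherP(ptab, sided = "two_sided"), 1)
  expect_gt(fisherP(ptab, sided = "one_sided_greater"), 0.5)
})

test_that("process contingency flags untestable processes and spots planted enrichment", {
  atlas <- toyAtlas()
  net <- buildProcessNetwork(atlas, "GO:0002711")
  expect_error(processContingency(atlas, net, "GO:0050900"),
               NA) # annotated in atlas: testable
  ## a term annotated nowhere is untestable
  atlas2 <- makeAtlas(list("GO:R" = character(0), "GO:A" = "GO:R",
                           "GO:NONE" = "GO:R"),
                      annotations = list(P1 = "GO:A"),
                      metaboliteLinks = list(M1 = "P1"))
  net2 <- buildProcessNetwork(atlas2, "GO:A")
  expect_error(processContingency(atlas2, net2, "GO:NONE"), "untestable")

  ## a process 10x enriched in the queried subnetwork attains the minimum p
  ann <- c(lapply(sprintf("E%02d", 1:10), function(i) "GO:X"),
           lapply(sprintf("O%02d", 1:20), function(i)
             c("GO:Y1", "GO:Y2", "GO:Y3")))
  names(ann) <- c(sprintf("E%02d", 1:10), sprintf("O%02d", 1:20))
  atlas3 <- makeAtlas(list("GO:R" = character(0), "GO:X" = "GO:R",
                           "GO:Y1" = "GO:R", "GO:Y2" = "GO:R",
                           "GO:Y3" = "GO:R"),
                      annotations = ann,
                      metaboliteLinks = list(M1 = "E01"))
  net3 <- buildProcessNetwork(atlas3, "GO:X")
  ps <- vapply(c("GO:X", "GO:Y1", "GO:Y2", "GO:Y3"), function(j)
    fisherP(processContingency(atlas3, net3, j)), numeric(1))
  expect_identical(names(which.min(ps)), "GO:X")
})

test_that("association ranking on the toy reproduces the worked-example structure", {
  atlas <- toyAtlas()
  net <- buildProcessNetwork(atlas, "GO:0002711")
  tab <- rankAssociations(atlas, net)
  sub <- tab[tab$process_id == "GO:0002711", ]
  expect_identical(nrow(sub), 8L)
  ## co-attached metabolites share one centrality value
  expect_length(unique(sub$centrality[sub$metabolite_id %in%
                                        paste0("MB0", 1:5)]), 1L)
  ## the exclusive metabolite attains the maximum ratio precision of 1
  expect_equal(max(sub$precision), 1)
  expect_identical(sub$metabolite_id[which.max(sub$precision)], "MB05")
  ## table-wide invariants
  expect_true(all(tab$q >= tab$p))
  expect_identical(tab$significant, tab$q < 0.05)
  expect_true(!is.unsorted(tab$q))
})

test_that("biomarker selection applies the mean-plus-2SD rule on significant rows only", {
  base <- data.frame(metabolite_id = sprintf("M%02d", 1:8),
                     process_id = "GO:A",
                     centrality = c(rep(0.4, 7), 0.95),
                     precision = c(rep(0.3, 7), 0.9),
                     significant = TRUE, stringsAsFactors = FALSE)
  picked <- selectBiomarkers(base)
  expect_identical(picked$metabolite_id, "M08")
  expect_true(all(picked$biomarker))

  ## a non-significant extreme row is never flagged
  base2 <- base
  base2$significant[8] <- FALSE
  expect_identical(nrow(selectBiomarkers(base2)), 0L)

  ## identical scores: sd = 0, nothing strictly exceeds the threshold
  flat <- base
  flat$centrality <- 0.5
  flat$precision <- 0.5
  expect_identical(nrow(selectBiomarkers(flat)), 0L)

  ## fewer than two significant rows: threshold undefined
  few <- base[1, ]
  expect_warning(out <- selectBiomarkers(few), "fewer than 2")
  expect_identical(nrow(out), 0L)
})

test_that("superclass summaries conserve metabolites and honour exclusions", {
  atlas <- toyAtlas()
  net <- buildProcessNetwork(atlas, "GO:0002711")
  tab <- rankAssociations(atlas, net)
  gmap <- c("GO:0002711" = "adaptive immunity")
  sum1 <- summarizeSuperclasses(tab, atlas, group_map = gmap)
  expect_setequal(unique(sum1$group), c("adaptive immunity", "other"))
  ## conservation: per-group totals count each distinct metabolite once
  adaptive <- sum1[sum1$group == "adaptive immunity", ]
  expect_identical(sum(adaptive$n_metabolites),
                   length(unique(tab$metabolite_id[
                     tab$process_id == "GO:0002711"])))
  ## excluded superclasses vanish entirely
  sum2 <- summarizeSuperclasses(tab, atlas, group_map = gmap,
                                exclude_superclasses =
                                  "Nucleosides, nucleotides, and analogues")
  expect_false("Nucleosides, nucleotides, and analogues" %in% sum2$superclass)
  hand <- length(unique(tab$metabolite_id[
    tab$process_id == "GO:0002711" &
      !tab$metabolite_id %in% c("MB06", "MB07", "MB08")]))
  expect_identical(sum(sum2$n_metabolites[sum2$group == "adaptive immunity"]),
                   hand)
})
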