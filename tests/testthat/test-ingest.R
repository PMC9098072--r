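test_that("ontology reader keeps the root's descendants and drops unreachable terms", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "go_terms.tsv")
  writeLines(c("term_id\tname\tparent_ids",
               "GO:0002376\timmune system process\t",
               "GO:0002711\tpositive regulation of T cell mediated immunity\tGO:0002376",
               "GO:9999999\tunrelated process\tGO:7777777"),
             path)
  expect_message(ont <- readGoTerms(path), "not reachable")
  expect_s4_class(ont, "ProcessOntology")
  expect_setequal(ontologyTerms(ont)$term_id, c("GO:0002376", "GO:0002711"))
  expect_identical(ontologyRoot(ont), "GO:0002376")
})

test_that("ontology reader rejects missing columns and parent cycles", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("term_id\tname", "GO:0002376\troot"), bad)
  expect_error(readGoTerms(bad), "schema error")
  cyc <- file.path(dir, "cycle.tsv")
  writeLines(c("term_id\tname\tparent_ids",
               "GO:0002376\troot\t",
               "GO:A\ta\tGO:B|GO:0002376",
               "GO:B\tb\tGO:A"),
             cyc)
  expect_error(readGoTerms(cyc), "cycle")
})

test_that("protein reader drops unknown annotations per protein but keeps the protein", {
  dir <- withr::local_tempdir()
  go <- file.path(dir, "go.tsv")
  writeLines(c("term_id\tname\tparent_ids",
               "GO:0002376\troot\t",
               "GO:0002711\tchild\tGO:0002376"), go)
  ont <- readGoTerms(go, quiet = TRUE)
  pr <- file.path(dir, "proteins.tsv")
  writeLines(c("protein_id\tname\tprocess_ids",
               "P1\tone\tGO:0002711",
               "P2\ttwo\tGO:MISSING"), pr)
  expect_message(cat <- readProteins(pr, ont), "unknown terms")
  expect_identical(processAnnotations(cat)$P1, "GO:0002711")
  expect_identical(processAnnotations(cat)$P2, character(0))
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("protein_id\tname\tprocess_ids",
               "P1\tone\t", "P1\tbis\t"), dup)
  expect_error(readProteins(dup, ont), "duplicate protein_id")
})

test_that("metabolite filters drop synthetic and inorganic rows", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "metabolites.tsv")
  writeLines(c(paste("metabolite_id", "name", "class", "superclass",
                     "is_biological", "is_inorganic", "protein_ids",
                     "compound_id", sep = "\t"),
               "M1\tkeep\tc\ts\t1\t0\tP1\tC1",
               "M2\tdrug\tc\ts\t0\t0\tP1\tC2",
               "M3\tmineral\tc\ts\t1\t1\tP1\tC3"),
             path)
  expect_message(cat <- readMetabolites(path), "excluded")
  expect_identical(metaboliteTable(cat)$metabolite_id, "M1")
})

test_that("PPI reader thresholds, canonicalizes, deduplicates keeping the max score", {
  dir <- withr::local_tempdir()
  go <- file.path(dir, "go.tsv")
  writeLines(c("term_id\tname\tparent_ids", "GO:0002376\troot\t"), go)
  ont <- readGoTerms(go, quiet = TRUE)
  pr <- file.path(dir, "proteins.tsv")
  writeLines(c("protein_id\tname\tprocess_ids",
               "P1\ta\tGO:0002376", "P2\tb\tGO:0002376",
               "P3\tc\t"), pr)
  cat <- readProteins(pr, ont, quiet = TRUE)
  ppi <- file.path(dir, "ppi.tsv")
  writeLines(c("protein_a\tprotein_b\tcombined_score",
               "P1\tP2\t300",     # duplicate pair, below threshold
               "P2\tP1\t800",     # duplicate pair, above
               "P1\tP1\t900",     # self-loop
               "P1\tP3\t700",
               "P1\tPX\t990"),    # unresolvable endpoint
             ppi)
  expect_message(es <- readPPI(ppi, cat, min_confidence = 400),
                 "unknown endpoints")
  e <- edgeTable(es)
  expect_identical(nrow(e), 2L)
  merged <- e[e$endpoint_a == "P1" & e$endpoint_b == "P2", ]
  expect_identical(merged$confidence, 800L)
  expect_false(any(e$endpoint_a == e$endpoint_b))

  bad <- file.path(dir, "bad_ppi.tsv")
  writeLines(c("protein_a\tprotein_b\tcombined_score", "P1\tP2\thigh"), bad)
  expect_error(readPPI(bad, cat), "schema error")
})

test_that("raising the PPI confidence threshold never adds edges", {
  dir <- withr::local_tempdir()
  fx <- generateFixture(fixtureConfig(seed = 11, n_proteins = 30,
                                      n_metabolites = 20,
                                      n_planted_committed = 1,
                                      n_background_per_plant = 4),
                        dir)
  ont <- readGoTerms(fx$paths[["go_terms"]], quiet = TRUE)
  cat <- readProteins(fx$paths[["proteins"]], ont, quiet = TRUE)
  prev <- Inf
  for (thr in c(0, 400, 700, 900)) {
    n <- nrow(edgeTable(readPPI(fx$paths[["ppi"]], cat,
                                min_confidence = thr, quiet = TRUE)))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("PMI links to proteins without immune annotations are excluded", {
  atlas <- toyAtlas()
  e <- edgeTable(atlas)
  pmi <- e[e$edge_type == "PMI", ]
  ## PR09 carries no immune process: its links (from MB04, MB09) must be gone
  expect_false(any(pmi$endpoint_a == "PR09" | pmi$endpoint_b == "PR09"))
  ## every PMI endpoint protein carries at least one process
  ann <- processAnnotations(atlas)
  prots <- intersect(unique(c(pmi$endpoint_a, pmi$endpoint_b)), names(ann))
  expect_true(all(lengths(ann[prots]) > 0))
})

test_that("reaction expansion is all-versus-all without self-pairs", {
  met <- metaboliteCatalog(
    data.frame(metabolite_id = c("A", "B", "C", "D"),
               name = c("a", "b", "c", "d"), class = "x", superclass = "s",
               is_biological = 1L, is_inorganic = 0L,
               compound_id = c("cA", "cB", "cC", "cD")),
    proteinLinks = list(A = character(0), B = character(0),
                        C = character(0), D = character(0)),
    quiet = TRUE)
  dir <- withr::local_tempdir()
  rx <- file.path(dir, "reactions.tsv")
  writeLines(c("reaction_id\treactant_ids\tproduct_ids",
               "R1\tcA|cB\tcC",
               "R2\tcA\tcA|cB",
               "R3\tcA|cB\tcC|cD"),
             rx)
  es <- expandReactions(rx, met, quiet = TRUE)
  e <- edgeTable(es)
  ## R1 contributes (A,C),(B,C); R2 only (A,B); R3 adds (A,D),(B,D)
  expect_setequal(paste(e$endpoint_a, e$endpoint_b),
                  c("A C", "B C", "A B", "A D", "B D"))
  expect_false(any(e$endpoint_a == e$endpoint_b))
})

test_that("atlas assembly records provenance and rejects dangling endpoints", {
  atlas <- toyAtlas()
  prov <- provenanceTable(atlas)
  expect_identical(nrow(prov), 5L)
  expect_identical(prov$rows[basename(prov$source) == "proteins.tsv"], 9L)
  expect_identical(prov$rows[basename(prov$source) == "metabolites.tsv"], 11L)

  parents <- list("GO:R" = character(0))
  ont <- processOntology(data.frame(term_id = "GO:R", name = "root"),
                         parents, "GO:R", quiet = TRUE)
  prot <- proteinCatalog(data.frame(protein_id = "P1", name = "p"),
                         list(P1 = "GO:R"), ont, quiet = TRUE)
  met <- metaboliteCatalog(
    data.frame(metabolite_id = "M1", name = "m", class = "c",
               superclass = "s", is_biological = 1L, is_inorganic = 0L,
               compound_id = "C1"),
    list(M1 = character(0)), quiet = TRUE)
  expect_error(
    assembleAtlas(ont, prot, met,
                  ppi = edgeSet("P1", "PGHOST", "PPI", 900L)),
    "dangling")
  ok <- assembleAtlas(ont, prot, met)
  expect_identical(nrow(edgeTable(ok)), 0L)
})

test_that("an atlas written to tables and re-read has equal node and edge sets", {
  for (seed in c(3, 17)) {
    atlas <- randomAtlas(seed)
    dir <- withr::local_tempdir()
    manifest <- writeAtlasTables(atlas, dir)
    back <- readAtlas(manifest, quiet = TRUE)
    expect_setequal(proteinTable(back)$protein_id,
                    proteinTable(atlas)$protein_id)
    expect_setequal(metaboliteTable(back)$metabolite_id,
                    metaboliteTable(atlas)$metabolite_id)
    expect_identical(edgeTable(back)[c("endpoint_a", "endpoint_b",
                                       "edge_type", "confidence")],
                     edgeTable(atlas)[c("endpoint_a", "endpoint_b",
                                        "edge_type", "confidence")])
  }
})

test_that("edge canonicalization is idempotent and never keeps loops or duplicates", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(3:10, 1)
    ids <- sample(LETTERS[1:6], n, replace = TRUE)
    ids2 <- sample(LETTERS[1:6], n, replace = TRUE)
    es <- edgeSet(ids, ids2, "PPI", sample(0:1000, n, replace = TRUE))
    e <- edgeTable(es)
    expect_true(validObject(es))
    again <- edgeSet(e$endpoint_a, e$endpoint_b, e$edge_type, e$confidence)
    expect_identical(edgeTable(again), e)
  }
})
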