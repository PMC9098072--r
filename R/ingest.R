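## Readers for the five database-style TSV inputs and atlas assembly.
## Dialect: UTF-8, tab-separated, header row required, "|" as in-cell list
## separator, empty string = absent.

#' Read immune-process terms
#'
#' Parses a GO-style term table and restricts it to the declared root and
#' its descendants. Terms without a parent path to the root are dropped
#' with a warning-level message; a parent cycle is a validation error.
#'
#' @param path TSV with columns \code{term_id}, \code{name},
#'   \code{parent_ids} (pipe-separated).
#' @param root root accession; defaults to the immune system process term.
#' @param quiet suppress messages.
#' @return A [ProcessOntology-class].
#' @export
readGoTerms <- function(path, root = "GO:0002376", quiet = FALSE) {
  df <- readTsv(path, c("term_id", "name", "parent_ids"))
  parents <- splitPipe(df$parent_ids)
  names(parents) <- df$term_id
  ont <- processOntology(df[c("term_id", "name")], parents, root,
                         quiet = quiet)
  attr(ont, "provenance") <- nrow(df)
  ont
}

#' Read the protein catalog
#'
#' @param path TSV with columns \code{protein_id}, \code{name},
#'   \code{process_ids} (pipe-separated).
#' @param ontology a [ProcessOntology-class]; annotations to terms outside
#'   it are dropped per protein.
#' @param quiet suppress messages.
#' @return A [ProteinCatalog-class]. Proteins may carry empty process sets
#'   at this stage; they are excluded from metabolite links later by
#'   [buildPMI()].
#' @export
readProteins <- function(path, ontology, quiet = FALSE) {
  df <- readTsv(path, c("protein_id", "name", "process_ids"))
  procs <- splitPipe(df$process_ids)
  names(procs) <- df$protein_id
  cat <- proteinCatalog(df[c("protein_id", "name")], procs, ontology,
                        quiet = quiet)
  attr(cat, "provenance") <- nrow(df)
  cat
}

#' Read the metabolite catalog
#'
#' Applies the inclusion filters: only metabolites with a biological role
#' (\code{is_biological = 1}) that are not inorganic compounds
#' (\code{is_inorganic = 0}) are retained.
#'
#' @param path TSV with columns \code{metabolite_id}, \code{name},
#'   \code{class}, \code{superclass}, \code{is_biological},
#'   \code{is_inorganic}, \code{protein_ids} (pipe-separated),
#'   \code{compound_id}.
#' @param quiet suppress messages.
#' @return A [MetaboliteCatalog-class] of retained rows.
#' @export
readMetabolites <- function(path, quiet = FALSE) {
  df <- readTsv(path, c("metabolite_id", "name", "class", "superclass",
                        "is_biological", "is_inorganic", "protein_ids",
                        "compound_id"))
  links <- splitPipe(df$protein_ids)
  names(links) <- df$metabolite_id
  cat <- metaboliteCatalog(df, links, quiet = quiet)
  attr(cat, "provenance") <- nrow(df)
  cat
}

#' Read STRING-style protein-protein interactions
#'
#' Edges below the confidence threshold are dropped, endpoints must resolve
#' in the catalog, self-loops are removed, and duplicate rows are merged
#' keeping the maximum combined score.
#'
#' @param path TSV with columns \code{protein_a}, \code{protein_b},
#'   \code{combined_score} (integer, STRING 0-1000 scale).
#' @param catalog a [ProteinCatalog-class].
#' @param min_confidence minimum combined score retained; the default 400
#'   is STRING's "medium confidence" cut.
#' @param quiet suppress messages.
#' @return An [EdgeSet-class] of PPI edges.
#' @export
readPPI <- function(path, catalog, min_confidence = 400, quiet = FALSE) {
  df <- readTsv(path, c("protein_a", "protein_b", "combined_score"))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score) || any(score != as.integer(score)))
    stop("schema error: non-integer combined_score in ", basename(path),
         call. = FALSE)
  score <- as.integer(score)
  keep <- score >= min_confidence
  known <- catalog@proteins$protein_id
  resolved <- df$protein_a %in% known & df$protein_b %in% known
  nUnresolved <- sum(keep & !resolved)
  if (nUnresolved > 0)
    imnMessage(nUnresolved, " PPI row(s) with unknown endpoints dropped",
               quiet = quiet)
  keep <- keep & resolved
  es <- edgeSet(df$protein_a[keep], df$protein_b[keep], "PPI", score[keep])
  attr(es, "provenance") <- nrow(df)
  es
}

#' Derive protein-metabolite interaction edges
#'
#' One PMI edge per (metabolite, protein) link where the protein carries at
#' least one immune-process annotation; links to proteins without immune
#' annotations are dropped and counted, and unresolvable protein ids are
#' logged but not fatal.
#'
#' @param metabolites a [MetaboliteCatalog-class].
#' @param proteins a [ProteinCatalog-class].
#' @param quiet suppress messages.
#' @return An [EdgeSet-class] of PMI edges.
#' @export
buildPMI <- function(metabolites, proteins, quiet = FALSE) {
  links <- metabolites@proteinLinks
  known <- proteins@proteins$protein_id
  immune <- known[lengths(proteins@processes[known]) > 0]
  m <- rep(names(links), lengths(links))
  p <- unlist(links, use.names = FALSE)
  if (length(m) == 0) return(edgeSet())
  unresolved <- !(p %in% known)
  if (any(unresolved))
    imnMessage(sum(unresolved), " metabolite-protein link(s) to unknown ",
               "proteins ignored", quiet = quiet)
  nonImmune <- (p %in% known) & !(p %in% immune)
  if (any(nonImmune))
    imnMessage(sum(nonImmune), " link(s) to proteins without immune-process ",
               "annotations excluded", quiet = quiet)
  keep <- p %in% immune
  edgeSet(m[keep], p[keep], "PMI")
}

#' Expand reaction participant lists into metabolite-metabolite edges
#'
#' All-versus-all expansion: every reactant-product combination of a
#' reaction becomes one undirected MMI edge. Self-pairs are excluded and
#' duplicates across reactions merged. Compound ids are mapped to
#' metabolite ids through the catalog's \code{compound_id} column; unmapped
#' ids are logged, not fatal.
#'
#' @param path TSV with columns \code{reaction_id}, \code{reactant_ids},
#'   \code{product_ids} (pipe-separated compound ids).
#' @param metabolites a [MetaboliteCatalog-class].
#' @param quiet suppress messages.
#' @return An [EdgeSet-class] of MMI edges.
#' @export
expandReactions <- function(path, metabolites, quiet = FALSE) {
  df <- readTsv(path, c("reaction_id", "reactant_ids", "product_ids"))
  mt <- metabolites@metabolites
  map <- stats::setNames(mt$metabolite_id, mt$compound_id)
  map <- map[nzchar(names(map))]
  reactants <- splitPipe(df$reactant_ids)
  products <- splitPipe(df$product_ids)
  aAll <- character(0); bAll <- character(0)
  nUnmapped <- 0L
  for (i in seq_len(nrow(df))) {
    r <- map[reactants[[i]]]
    p <- map[products[[i]]]
    nUnmapped <- nUnmapped + sum(is.na(r)) + sum(is.na(p))
    r <- r[!is.na(r)]; p <- p[!is.na(p)]
    if (length(r) == 0 || length(p) == 0) next
    grid <- expand.grid(a = r, b = p, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    aAll <- c(aAll, grid$a)
    bAll <- c(bAll, grid$b)
  }
  if (nUnmapped > 0)
    imnMessage(nUnmapped, " reaction compound id(s) not mapped to retained ",
               "metabolites", quiet = quiet)
  es <- edgeSet(aAll, bAll, "MMI")
  attr(es, "provenance") <- nrow(df)
  es
}

#' Assemble the atlas database
#'
#' Merges the validated components into a single background store with an
#' igraph index for neighbour and association lookup. A dangling edge
#' endpoint after all filters is a validation error.
#'
#' @param ontology a [ProcessOntology-class].
#' @param proteins a [ProteinCatalog-class].
#' @param metabolites a [MetaboliteCatalog-class].
#' @param ppi,pmi,mmi [EdgeSet-class] objects (may be empty).
#' @param provenance optional data.frame (source, rows) recording input row
#'   counts; assembled automatically by [readAtlas()].
#' @return An [AtlasDB-class].
#' @export
assembleAtlas <- function(ontology, proteins, metabolites,
                          ppi = edgeSet(), pmi = edgeSet(), mmi = edgeSet(),
                          provenance = NULL) {
  edges <- mergeEdgeSets(ppi, pmi, mmi)
  prot <- proteins@proteins$protein_id
  met <- metabolites@metabolites$metabolite_id
  e <- edges@edges
  dangling <- setdiff(unique(c(e$endpoint_a, e$endpoint_b)), c(prot, met))
  if (length(dangling) > 0)
    stop("validation error: dangling edge endpoint(s): ",
         paste(utils::head(dangling, 5), collapse = ", "), call. = FALSE)
  if (is.null(provenance))
    provenance <- data.frame(source = character(0), rows = integer(0),
                             stringsAsFactors = FALSE)
  vert <- data.frame(
    name = c(prot, met),
    kind = c(rep("protein", length(prot)), rep("metabolite", length(met))),
    label = c(proteins@proteins$name, metabolites@metabolites$name),
    superclass = c(rep(NA_character_, length(prot)),
                   metabolites@metabolites$superclass),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$endpoint_a, to = e$endpoint_b,
               edge_type = e$edge_type, confidence = e$confidence,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = vert)
  new("AtlasDB", ontology = ontology, proteins = proteins,
      metabolites = metabolites, edges = edges, graph = g,
      provenance = provenance)
}

#' Read an atlas from a JSON build manifest
#'
#' The manifest names the five input tables plus the root term and PPI
#' confidence threshold:
#' \preformatted{
#' {"go_terms": "go_terms.tsv", "proteins": "proteins.tsv",
#'  "metabolites": "metabolites.tsv", "ppi": "ppi.tsv",
#'  "reactions": "reactions.tsv",
#'  "root": "GO:0002376", "min_confidence": 400}
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param manifest path to the JSON manifest.
#' @param min_confidence override of the manifest's PPI threshold.
#' @param quiet suppress messages.
#' @return An [AtlasDB-class] with provenance row counts per input.
#' @export
readAtlas <- function(manifest, min_confidence = NULL, quiet = FALSE) {
  cfg <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  need <- c("go_terms", "proteins", "metabolites", "ppi", "reactions")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("manifest missing entries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir <- dirname(manifest)
  paths <- vapply(need, function(k) {
    p <- cfg[[k]]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(dir, p)
    p
  }, character(1))
  root <- if (!is.null(cfg$root)) cfg$root else "GO:0002376"
  if (is.null(min_confidence))
    min_confidence <- if (!is.null(cfg$min_confidence)) cfg$min_confidence else 400
  ont <- readGoTerms(paths["go_terms"], root = root, quiet = quiet)
  prot <- readProteins(paths["proteins"], ont, quiet = quiet)
  met <- readMetabolites(paths["metabolites"], quiet = quiet)
  ppi <- readPPI(paths["ppi"], prot, min_confidence = min_confidence,
                 quiet = quiet)
  pmi <- buildPMI(met, prot, quiet = quiet)
  mmi <- expandReactions(paths["reactions"], met, quiet = quiet)
  prov <- data.frame(
    source = unname(paths),
    rows = c(attr(ont, "provenance"), attr(prot, "provenance"),
             attr(met, "provenance"), attr(ppi, "provenance"),
             attr(mmi, "provenance")),
    stringsAsFactors = FALSE)
  assembleAtlas(ont, prot, met, ppi, pmi, mmi, provenance = prov)
}

#' Write an atlas back to the five-table format
#'
#' Emits \code{go_terms.tsv}, \code{proteins.tsv}, \code{metabolites.tsv},
#' \code{ppi.tsv}, \code{reactions.tsv} and \code{manifest.json} reflecting
#' the filtered state of the atlas, so that re-reading reproduces the same
#' node and edge sets. MMI edges are written as one two-participant
#' reaction per edge (the all-versus-all expansion is not invertible).
#'
#' @param atlas an [AtlasDB-class].
#' @param dir output directory (created if absent).
#' @param min_confidence threshold recorded in the manifest; defaults to 0
#'   because the atlas edges are already filtered.
#' @return Invisibly, the manifest path.
#' @export
writeAtlasTables <- function(atlas, dir, min_confidence = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ont <- atlas@ontology
  writeTsv(data.frame(term_id = ont@terms$term_id, name = ont@terms$name,
                      parent_ids = joinPipe(ont@parents[ont@terms$term_id]),
                      stringsAsFactors = FALSE),
           file.path(dir, "go_terms.tsv"))
  pc <- atlas@proteins
  writeTsv(data.frame(protein_id = pc@proteins$protein_id,
                      name = pc@proteins$name,
                      process_ids = joinPipe(pc@processes[pc@proteins$protein_id]),
                      stringsAsFactors = FALSE),
           file.path(dir, "proteins.tsv"))
  e <- atlas@edges@edges
  pmi <- e[e$edge_type == "PMI", , drop = FALSE]
  mc <- atlas@metabolites
  metIds <- mc@metabolites$metabolite_id
  pmiLinks <- lapply(metIds, function(m) {
    sort(unique(c(pmi$endpoint_b[pmi$endpoint_a == m],
                  pmi$endpoint_a[pmi$endpoint_b == m])))
  })
  names(pmiLinks) <- metIds
  writeTsv(data.frame(metabolite_id = metIds,
                      name = mc@metabolites$name,
                      class = mc@metabolites$class,
                      superclass = mc@metabolites$superclass,
                      is_biological = 1L, is_inorganic = 0L,
                      protein_ids = joinPipe(pmiLinks),
                      compound_id = mc@metabolites$compound_id,
                      stringsAsFactors = FALSE),
           file.path(dir, "metabolites.tsv"))
  ppi <- e[e$edge_type == "PPI", , drop = FALSE]
  writeTsv(data.frame(protein_a = ppi$endpoint_a, protein_b = ppi$endpoint_b,
                      combined_score = ppi$confidence,
                      stringsAsFactors = FALSE),
           file.path(dir, "ppi.tsv"))
  mmi <- e[e$edge_type == "MMI", , drop = FALSE]
  cmpd <- stats::setNames(mc@metabolites$compound_id, metIds)
  writeTsv(data.frame(
    reaction_id = if (nrow(mmi)) sprintf("RX%05d", seq_len(nrow(mmi))) else character(0),
    reactant_ids = unname(cmpd[mmi$endpoint_a]),
    product_ids = unname(cmpd[mmi$endpoint_b]),
    stringsAsFactors = FALSE),
    file.path(dir, "reactions.tsv"))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(go_terms = "go_terms.tsv", proteins = "proteins.tsv",
         metabolites = "metabolites.tsv", ppi = "ppi.tsv",
         reactions = "reactions.tsv", root = ont@root,
         min_confidence = min_confidence),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
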