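## Seeded synthetic atlas inputs with planted structure, plus the packaged
## miniature T-cell atlas.

#' Configuration for the synthetic fixture generator
#'
#' Validates and completes a generator configuration. A single integer
#' seed governs all randomness; identical seed and configuration produce
#' byte-identical files.
#'
#' @param seed integer seed.
#' @param n_processes total ontology terms including the root.
#' @param n_proteins protein catalog size.
#' @param n_metabolites metabolite rows written (including planted
#'   excluded rows).
#' @param frac_immune_proteins fraction of proteins carrying immune-process
#'   annotations.
#' @param ppi_density Erdos-Renyi edge probability among immune proteins
#'   (a star around each process hub is added on top, so both connected
#'   hubs and singletons occur).
#' @param pmi_per_metabolite mean protein links per filler metabolite
#'   (Poisson).
#' @param n_reactions reaction rows.
#' @param n_planted_committed metabolites wired exclusively to one
#'   process's proteins (ratio-precision 1 in that process).
#' @param n_planted_isolated metabolites with zero protein links.
#' @param n_planted_synthetic rows flagged without biological role
#'   (excluded at ingest).
#' @param n_planted_inorganic rows flagged inorganic (excluded at ingest).
#' @param n_background_per_plant cohort size of moderately linked
#'   metabolites wired into each committed plant's target process.
#' @param n_proteins_per_target immune proteins dedicated (and annotated
#'   exclusively) to each committed plant's target process.
#' @param superclass_labels chemical superclass labels sampled for
#'   metabolites.
#' @return A validated list of class \code{fixture_config}.
#' @export
fixtureConfig <- function(seed = 1L,
                          n_processes = 12L,
                          n_proteins = 80L,
                          n_metabolites = 60L,
                          frac_immune_proteins = 0.6,
                          ppi_density = 0.04,
                          pmi_per_metabolite = 2,
                          n_reactions = 10L,
                          n_planted_committed = 2L,
                          n_planted_isolated = 3L,
                          n_planted_synthetic = 3L,
                          n_planted_inorganic = 2L,
                          n_background_per_plant = 9L,
                          n_proteins_per_target = 6L,
                          superclass_labels = c(
                            "Lipids and lipid-like molecules",
                            "Organic acids and derivatives",
                            "Nucleosides, nucleotides, and analogues",
                            "Organic nitrogen compounds",
                            "Organic oxygen compounds",
                            "Benzenoids")) {
  cfg <- list(seed = as.integer(seed), n_processes = as.integer(n_processes),
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites),
              frac_immune_proteins = frac_immune_proteins,
              ppi_density = ppi_density,
              pmi_per_metabolite = pmi_per_metabolite,
              n_reactions = as.integer(n_reactions),
              n_planted_committed = as.integer(n_planted_committed),
              n_planted_isolated = as.integer(n_planted_isolated),
              n_planted_synthetic = as.integer(n_planted_synthetic),
              n_planted_inorganic = as.integer(n_planted_inorganic),
              n_background_per_plant = as.integer(n_background_per_plant),
              n_proteins_per_target = as.integer(n_proteins_per_target),
              superclass_labels = as.character(superclass_labels))
  counts <- cfg[c("n_processes", "n_proteins", "n_metabolites",
                  "n_reactions", "n_planted_committed", "n_planted_isolated",
                  "n_planted_synthetic", "n_planted_inorganic")]
  if (any(unlist(counts) < 0))
    stop("config error: counts must be nonnegative", call. = FALSE)
  props <- c(cfg$frac_immune_proteins, cfg$ppi_density)
  if (any(props < 0 | props > 1))
    stop("config error: proportions must lie in [0, 1]", call. = FALSE)
  if (cfg$n_processes < 1)
    stop("config error: need at least the root process", call. = FALSE)
  nImmune <- round(cfg$frac_immune_proteins * cfg$n_proteins)
  if (cfg$n_planted_committed > 0) {
    if (nImmune < cfg$n_planted_committed * cfg$n_proteins_per_target)
      stop("config error: committed plants requested but too few immune ",
           "proteins to dedicate", call. = FALSE)
    if (cfg$n_processes - 1 < cfg$n_planted_committed)
      stop("config error: committed plants requested but too few processes",
           call. = FALSE)
  }
  nPlanted <- cfg$n_planted_committed * (1 + cfg$n_background_per_plant) +
    cfg$n_planted_isolated + cfg$n_planted_synthetic + cfg$n_planted_inorganic
  if (nPlanted > cfg$n_metabolites)
    stop("config error: planted metabolites exceed n_metabolites",
         call. = FALSE)
  class(cfg) <- "fixture_config"
  cfg
}

#' Generate seeded synthetic atlas inputs
#'
#' Writes the five ingest tables (\code{go_terms.tsv}, \code{proteins.tsv},
#' \code{metabolites.tsv}, \code{ppi.tsv}, \code{reactions.tsv}), a build
#' \code{manifest.json} and a \code{planted_truth.json} manifest recording,
#' for each planted committed metabolite, its target process, plus the
#' isolated and excluded plants. Identical seed and configuration yield
#' byte-identical files.
#'
#' @param config a [fixtureConfig()] result (or arguments for one).
#' @param out_dir output directory, created if absent.
#' @return Invisibly, a list with the written \code{paths} and the
#'   \code{truth} manifest.
#' @export
generateFixture <- function(config = fixtureConfig(), out_dir) {
  if (!inherits(config, "fixture_config")) config <- do.call(fixtureConfig, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  root <- "GO:0002376"

  ## --- ontology: random tree under the root ---------------------------
  nP <- config$n_processes
  termIds <- c(root, sprintf("GO:%07d", 3000000 + seq_len(max(nP - 1, 0))))
  parents <- character(length(termIds))
  parents[1] <- ""
  for (i in seq_len(nP - 1) + 1)
    parents[i] <- termIds[sample.int(i - 1, 1)]
  goDf <- data.frame(term_id = termIds,
                     name = c("immune system process",
                              sprintf("immune process %02d",
                                      seq_len(max(nP - 1, 0)))),
                     parent_ids = parents, stringsAsFactors = FALSE)

  ## --- proteins -------------------------------------------------------
  nPr <- config$n_proteins
  protIds <- sprintf("P%05d", seq_len(nPr))
  nImmune <- round(config$frac_immune_proteins * nPr)
  immune <- protIds[seq_len(nImmune)]
  nonRoot <- setdiff(termIds, root)
  targets <- utils::head(nonRoot, config$n_planted_committed)
  ann <- stats::setNames(vector("list", nPr), protIds)
  ann[] <- list(character(0))
  ## dedicated, exclusively annotated proteins per target process
  targetProts <- list()
  cursor <- 0L
  for (t in targets) {
    idx <- cursor + seq_len(config$n_proteins_per_target)
    targetProts[[t]] <- immune[idx]
    for (p in immune[idx]) ann[[p]] <- t
    cursor <- cursor + config$n_proteins_per_target
  }
  general <- setdiff(immune, unlist(targetProts))
  pool <- setdiff(nonRoot, targets)
  if (length(pool) == 0) pool <- nonRoot
  for (p in general)
    ann[[p]] <- sort(unique(sample(pool, size = sample(1:2, 1),
                                   replace = TRUE)))
  protDf <- data.frame(protein_id = protIds,
                       name = sprintf("protein %03d", seq_len(nPr)),
                       process_ids = joinPipe(ann[protIds]),
                       stringsAsFactors = FALSE)

  ## --- PPI: ER layer over immune proteins + star around process hubs --
  ppiA <- character(0); ppiB <- character(0)
  if (length(immune) >= 2) {
    pairs <- utils::combn(immune, 2)
    pick <- stats::runif(ncol(pairs)) < config$ppi_density
    ppiA <- pairs[1, pick]; ppiB <- pairs[2, pick]
  }
  for (t in names(targetProts)) {
    prots <- targetProts[[t]]
    if (length(prots) >= 2) {
      ppiA <- c(ppiA, rep(prots[1], length(prots) - 1))
      ppiB <- c(ppiB, prots[-1])
    }
  }
  byProc <- split(rep(names(ann), lengths(ann)),
                  unlist(ann, use.names = FALSE))
  for (t in setdiff(names(byProc), names(targetProts))) {
    prots <- unique(byProc[[t]])
    if (length(prots) >= 2) {
      ppiA <- c(ppiA, rep(prots[1], length(prots) - 1))
      ppiB <- c(ppiB, prots[-1])
    }
  }
  ppiDf <- data.frame(protein_a = ppiA, protein_b = ppiB,
                      combined_score = sample(400:999, length(ppiA),
                                              replace = TRUE),
                      stringsAsFactors = FALSE)
  ## a few sub-threshold rows exercising the confidence filter
  if (nPr >= 4) {
    low <- data.frame(protein_a = protIds[1:2], protein_b = protIds[3:4],
                      combined_score = sample(100:399, 2, replace = TRUE),
                      stringsAsFactors = FALSE)
    ppiDf <- rbind(ppiDf, low)
  }

  ## --- metabolites ----------------------------------------------------
  nM <- config$n_metabolites
  metIds <- sprintf("HMDB%07d", seq_len(nM))
  super <- sample(config$superclass_labels, nM, replace = TRUE)
  links <- stats::setNames(vector("list", nM), metIds)
  links[] <- list(character(0))
  isBio <- rep(1L, nM); isInorg <- rep(0L, nM)
  i <- 1L
  committed <- character(0)
  backgroundByTarget <- list()
  for (t in targets) {
    links[[metIds[i]]] <- targetProts[[t]]
    committed <- c(committed, metIds[i])
    i <- i + 1L
    bg <- character(0)
    for (k in seq_len(config$n_background_per_plant)) {
      inside <- sample(targetProts[[t]], 3)
      outside <- sample(general, sample(1:3, 1))
      links[[metIds[i]]] <- sort(unique(c(inside, outside)))
      bg <- c(bg, metIds[i])
      i <- i + 1L
    }
    backgroundByTarget[[t]] <- bg
  }
  isolated <- metIds[seq_len(config$n_planted_isolated) + i - 1L]
  i <- i + config$n_planted_isolated
  nonBioIdx <- seq_len(config$n_planted_synthetic) +
    (nM - config$n_planted_synthetic - config$n_planted_inorganic)
  inorgIdx <- seq_len(config$n_planted_inorganic) +
    (nM - config$n_planted_inorganic)
  isBio[nonBioIdx] <- 0L
  isInorg[inorgIdx] <- 1L
  fillerIdx <- if (i <= nM) setdiff(i:nM, c(nonBioIdx, inorgIdx)) else integer(0)
  linkPool <- c(general, protIds[seq_len(min(5, nPr - nImmune)) + nImmune])
  for (j in fillerIdx) {
    k <- stats::rpois(1, config$pmi_per_metabolite)
    if (k > 0)
      links[[metIds[j]]] <- sort(unique(sample(linkPool, min(k, length(linkPool)))))
  }
  if (length(immune) > 0)
    for (j in c(nonBioIdx, inorgIdx))
      links[[metIds[j]]] <- sample(immune, 1)
  metDf <- data.frame(metabolite_id = metIds,
                      name = sprintf("metabolite %03d", seq_len(nM)),
                      class = paste(super, "class"),
                      superclass = super,
                      is_biological = isBio, is_inorganic = isInorg,
                      protein_ids = joinPipe(links[metIds]),
                      compound_id = sprintf("CPD%05d", seq_len(nM)),
                      stringsAsFactors = FALSE)

  ## --- reactions over filler metabolites ------------------------------
  fillerCmp <- metDf$compound_id[fillerIdx]
  rxn <- data.frame(reaction_id = character(0), reactant_ids = character(0),
                    product_ids = character(0), stringsAsFactors = FALSE)
  if (length(fillerCmp) >= 3 && config$n_reactions > 0) {
    rows <- lapply(seq_len(config$n_reactions), function(r) {
      part <- sample(fillerCmp, sample(3:min(4, length(fillerCmp)), 1))
      nReac <- sample(seq_len(length(part) - 1), 1)
      data.frame(reaction_id = sprintf("RHEA%05d", r),
                 reactant_ids = paste(part[seq_len(nReac)], collapse = "|"),
                 product_ids = paste(part[-seq_len(nReac)], collapse = "|"),
                 stringsAsFactors = FALSE)
    })
    rxn <- do.call(rbind, rows)
  }

  paths <- c(go_terms = file.path(out_dir, "go_terms.tsv"),
             proteins = file.path(out_dir, "proteins.tsv"),
             metabolites = file.path(out_dir, "metabolites.tsv"),
             ppi = file.path(out_dir, "ppi.tsv"),
             reactions = file.path(out_dir, "reactions.tsv"))
  writeTsv(goDf, paths["go_terms"])
  writeTsv(protDf, paths["proteins"])
  writeTsv(metDf, paths["metabolites"])
  writeTsv(ppiDf, paths["ppi"])
  writeTsv(rxn, paths["reactions"])
  manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(go_terms = "go_terms.tsv", proteins = "proteins.tsv",
         metabolites = "metabolites.tsv", ppi = "ppi.tsv",
         reactions = "reactions.tsv", root = root, min_confidence = 400),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  truth <- list(
    seed = config$seed,
    committed = mapply(function(m, t) list(metabolite_id = m, process_id = t),
                       committed, targets, SIMPLIFY = FALSE, USE.NAMES = FALSE),
    isolated = as.list(isolated),
    excluded = as.list(metIds[c(nonBioIdx, inorgIdx)]),
    background = backgroundByTarget)
  truthPath <- file.path(out_dir, "planted_truth.json")
  jsonlite::write_json(truth, truthPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(paths = c(paths, manifest = manifest, truth = truthPath),
                 truth = truth))
}

#' Write the packaged miniature T-cell atlas
#'
#' Copies the checked-in miniature atlas emulating a positive-regulation-
#' of-T-cell-mediated-immunity query: one process of interest plus
#' background processes; five sphingoid-like metabolites sharing an
#' identical protein neighbour set inside the process (hence identical
#' centralities), one of which interacts with no protein outside the
#' process (ratio-precision 1); and three nucleotide-like metabolites
#' attached to peripheral proteins. The process network contains exactly
#' 8 metabolites.
#'
#' @param out_dir destination directory (created if absent).
#' @return Invisibly, the path of the copied manifest.
#' @export
tcellToy <- function(out_dir) {
  src <- system.file("extdata", "tcell_toy", package = "immunet",
                     mustWork = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ok <- file.copy(list.files(src, full.names = TRUE), out_dir,
                  overwrite = TRUE)
  if (!all(ok)) stop("failed to copy toy fixture files", call. = FALSE)
  invisible(file.path(out_dir, "manifest.json"))
}

#' Load the packaged miniature T-cell atlas
#'
#' @param quiet suppress ingest messages (default TRUE).
#' @return An [AtlasDB-class] built from the packaged tables.
#' @seealso [tcellToy()]
#' @export
loadTcellToy <- function(quiet = TRUE) {
  src <- system.file("extdata", "tcell_toy", "manifest.json",
                     package = "immunet", mustWork = TRUE)
  readAtlas(src, quiet = quiet)
}
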