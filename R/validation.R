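## Gold-standard evaluation: occurrence filtering, confusion metrics and
## the order-comparison table.

#' Read a gold-standard pair-count table
#'
#' @param path TSV with columns \code{metabolite_id}, \code{process_id},
#'   \code{occurrence_count}.
#' @return data.frame with those columns (counts integer).
#' @export
readGoldStandard <- function(path) {
  df <- readTsv(path, c("metabolite_id", "process_id", "occurrence_count"))
  df$occurrence_count <- as.integer(df$occurrence_count)
  if (any(is.na(df$occurrence_count) | df$occurrence_count < 0))
    stop("occurrence_count must be nonnegative integers", call. = FALSE)
  df
}

#' Filter a text-mining gold standard
#'
#' Pairs observed only once are removed to limit false positives (the
#' default minimum occurrence count is 2), and pairs whose metabolite
#' belongs to an excluded superclass (typically lipids and lipid-like
#' molecules, whose nomenclature defeats text mining) are removed
#' regardless of count.
#'
#' @param gold data.frame with columns \code{metabolite_id},
#'   \code{process_id}, \code{occurrence_count}, or a path to such a TSV.
#' @param min_count minimum occurrence count retained (default 2).
#' @param exclude_superclasses character vector of superclasses to remove.
#' @param superclass_map named character vector metabolite_id -> superclass
#'   (e.g. from [metaboliteTable()]); required when
#'   \code{exclude_superclasses} is nonempty.
#' @param quiet suppress messages.
#' @return data.frame of retained pairs with columns \code{metabolite_id},
#'   \code{process_id}, \code{occurrence_count}.
#' @export
filterGoldStandard <- function(gold, min_count = 2,
                               exclude_superclasses = character(0),
                               superclass_map = NULL, quiet = FALSE) {
  if (is.character(gold) && length(gold) == 1) gold <- readGoldStandard(gold)
  n0 <- nrow(gold)
  keep <- gold$occurrence_count >= min_count
  nLow <- sum(!keep)
  gold <- gold[keep, , drop = FALSE]
  nClass <- 0L
  if (length(exclude_superclasses) > 0) {
    if (is.null(superclass_map))
      stop("superclass exclusion requires superclass_map", call. = FALSE)
    sc <- unname(superclass_map[gold$metabolite_id])
    drop <- !is.na(sc) & sc %in% exclude_superclasses
    nClass <- sum(drop)
    gold <- gold[!drop, , drop = FALSE]
  }
  imnMessage("gold standard: ", n0, " pairs; removed ", nLow,
             " below count ", min_count, " and ", nClass,
             " in excluded superclasses; ", nrow(gold), " retained",
             quiet = quiet)
  gold <- gold[base::order(gold$metabolite_id, gold$process_id), ,
               drop = FALSE]
  rownames(gold) <- NULL
  gold
}

#' Confusion summary of predicted versus gold-standard associations
#'
#' Counts TP, FP, FN and TN over a declared universe of candidate
#' (metabolite, process) pairs and derives specificity, sensitivity,
#' precision, accuracy and the F1 score
#' (TP / (TP + 0.5 (FP + FN))). Ratios with a zero denominator are
#' reported as \code{NA}, not 0.
#'
#' @param predicted data.frame of predicted pairs (columns
#'   \code{metabolite_id}, \code{process_id}).
#' @param gold data.frame of gold-standard pairs (same columns).
#' @param universe data.frame of all candidate pairs; both inputs must be
#'   subsets of it.
#' @return One-row data.frame with columns \code{TP}, \code{TN}, \code{FP},
#'   \code{FN}, \code{specificity}, \code{sensitivity}, \code{precision},
#'   \code{accuracy}, \code{f1}, \code{universe_size}.
#' @export
confusionSummary <- function(predicted, gold, universe) {
  uKey <- unique(pairKey(universe$metabolite_id, universe$process_id))
  pKey <- unique(pairKey(predicted$metabolite_id, predicted$process_id))
  gKey <- unique(pairKey(gold$metabolite_id, gold$process_id))
  if (!all(pKey %in% uKey))
    stop("validation error: predicted pair(s) outside universe",
         call. = FALSE)
  if (!all(gKey %in% uKey))
    stop("validation error: gold pair(s) outside universe", call. = FALSE)
  TP <- length(intersect(pKey, gKey))
  FP <- length(setdiff(pKey, gKey))
  FN <- length(setdiff(gKey, pKey))
  TN <- length(uKey) - TP - FP - FN
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  data.frame(TP = TP, TN = TN, FP = FP, FN = FN,
             specificity = ratio(TN, TN + FP),
             sensitivity = ratio(TP, TP + FN),
             precision = ratio(TP, TP + FP),
             accuracy = ratio(TN + TP, TN + TP + FN + FP),
             f1 = ratio(TP, TP + 0.5 * (FP + FN)),
             universe_size = length(uKey))
}

#' Universe of candidate pairs of an atlas
#'
#' All (metabolite, process) pairs formable from the atlas's retained
#' metabolites and immune processes — the background over which true
#' negatives are counted.
#'
#' @param atlas an [AtlasDB-class].
#' @return data.frame with columns \code{metabolite_id}, \code{process_id}.
#' @export
atlasUniverse <- function(atlas) {
  expand.grid(metabolite_id = metaboliteTable(atlas)$metabolite_id,
              process_id = immuneProcesses(atlas),
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Compare inheritance orders against a gold standard
#'
#' Runs full-atlas inheritance at each requested order, evaluates the
#' predicted pairs against the same gold standard and universe, and
#' returns one confusion row per order. Gold pairs outside the atlas
#' universe are dropped with a warning.
#'
#' @param atlas an [AtlasDB-class].
#' @param gold data.frame of gold-standard pairs (e.g. from
#'   [filterGoldStandard()]).
#' @param orders integer vector of inheritance orders (subset of 1:3).
#' @return data.frame with an \code{order} column followed by the
#'   [confusionSummary()] columns.
#' @export
compareOrders <- function(atlas, gold, orders = 1:3) {
  universe <- atlasUniverse(atlas)
  uKey <- pairKey(universe$metabolite_id, universe$process_id)
  inU <- pairKey(gold$metabolite_id, gold$process_id) %in% uKey
  if (any(!inU)) {
    warning(sum(!inU), " gold pair(s) outside the atlas universe dropped",
            call. = FALSE)
    gold <- gold[inU, , drop = FALSE]
  }
  rows <- lapply(orders, function(k) {
    pred <- associationPairs(
      inheritProcesses(atlas, order = k, scope = "atlas"))
    cbind(data.frame(order = as.integer(k)),
          confusionSummary(pred, gold, universe))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
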