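## Internal helpers shared across modules.

#' @importFrom utils read.delim write.table
NULL

PIPE_SEP <- "|"

imnMessage <- function(..., quiet = FALSE) {
  if (!isTRUE(quiet)) message("immunet: ", ...)
  invisible(NULL)
}

## Split a pipe-separated cell into a character vector; "" means absent.
splitPipe <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  out <- strsplit(x, PIPE_SEP, fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

joinPipe <- function(x) {
  vapply(x, function(v) paste(v, collapse = PIPE_SEP), character(1))
}

## Read a UTF-8 tab-separated table with a header row, all columns character.
readTsv <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

writeTsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(signif(x, 6), format = "g", digits = 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8",
                     eol = "\n")
  invisible(path)
}

## Canonical undirected edge table: endpoint_a < endpoint_b, no self-loops,
## duplicates merged keeping the maximum confidence.
canonicalizeEdges <- function(a, b, type, confidence = NA_integer_) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  type <- rep_len(type, length(keep))[keep]
  confidence <- rep_len(confidence, length(keep))[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  df <- data.frame(endpoint_a = lo, endpoint_b = hi, edge_type = type,
                   confidence = as.integer(confidence),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(df)
  key <- paste(df$endpoint_a, df$endpoint_b, df$edge_type, sep = "\r")
  ord <- order(key, -ifelse(is.na(df$confidence), -1L, df$confidence))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(key[ord]), , drop = FALSE]
  df <- df[order(df$edge_type, df$endpoint_a, df$endpoint_b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

pairKey <- function(metabolite_id, process_id) {
  paste(metabolite_id, process_id, sep = "\r")
}

emptyEdgeFrame <- function() {
  data.frame(endpoint_a = character(0), endpoint_b = character(0),
             edge_type = character(0), confidence = integer(0),
             stringsAsFactors = FALSE)
}
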