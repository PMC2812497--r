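#' Hit tables: best-hit homology records
#'
#' A `HitTable` is a data frame of best-hit homology records with columns
#' `query`, `query_genome`, `subject`, `database` (subject genome or database
#' label), `evalue` and `bitscore`. After reduction it contains at most one
#' row per (query, database) pair: the lowest e-value, ties broken by highest
#' bit score, then lexicographic subject id.
#'
#' @param query,query_genome,subject,database,evalue,bitscore Column vectors.
#' @return A `HitTable` data frame.
#' @export
hit_table <- function(query = character(), query_genome = character(),
                      subject = character(), database = character(),
                      evalue = numeric(), bitscore = numeric()) {
  if (any(evalue < 0)) stop("negative e-value in hit table")
  if (any(!is.finite(bitscore))) stop("non-finite bit score in hit table")
  n <- length(query)
  structure(
    data.frame(query = as.character(query),
               query_genome = rep_len(as.character(query_genome), n),
               subject = as.character(subject),
               database = rep_len(as.character(database), n),
               evalue = rep_len(as.numeric(evalue), n),
               bitscore = rep_len(as.numeric(bitscore), n),
               stringsAsFactors = FALSE),
    class = c("HitTable", "data.frame"))
}

#' Read a 12-column tabular homology file
#'
#' Parses the standard 12-column tab-separated alignment format
#' (query, subject, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore) as emitted by `blastp -outfmt 6` and compatible
#' tools, and reduces it to best hits per (query, database).
#'
#' @param path Input path. An empty file yields an empty table.
#' @param database Database label assigned to all rows (default: file name
#'   without extension).
#' @param query_genome Query genome label (default `"query"`).
#' @param reduce Reduce to best hit per (query, database)? Default `TRUE`.
#' @return A [hit_table()].
#' @export
read_hit_table <- function(path, database = NULL, query_genome = "query",
                           reduce = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(database)) database <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(hit_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == 12L
  if (any(!ncol_ok)) {
    stop("expected 12 tab-separated columns at line ", which(!ncol_ok)[1])
  }
  m <- do.call(rbind, fields)
  ev <- suppressWarnings(as.numeric(m[, 11]))
  bs <- suppressWarnings(as.numeric(m[, 12]))
  bad <- which(is.na(ev) | is.na(bs))
  if (length(bad) > 0) {
    stop("non-numeric evalue/bitscore at line ", bad[1])
  }
  ht <- hit_table(query = m[, 1], query_genome = query_genome,
                  subject = m[, 2], database = database,
                  evalue = ev, bitscore = bs)
  if (reduce) reduce_best_hits(ht) else ht
}

#' Reduce a hit table to best hits
#'
#' Keeps, for each (query, database) pair, the single row with the lowest
#' e-value; ties are broken by highest bit score, then by lexicographically
#' smallest subject id.
#'
#' @param hits A [hit_table()].
#' @return The reduced `HitTable`.
#' @export
reduce_best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  o <- order(hits$query, hits$database, hits$evalue, -hits$bitscore,
             hits$subject)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(paste(hits$query, hits$database, sep = "\r"))
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("HitTable", "data.frame")
  out
}

#' Write a hit table in the 12-column tabular dialect
#'
#' Alignment coordinates are not tracked in reduced tables; the pident,
#' length, mismatch, gapopen and coordinate columns are written as 0 so that
#' the file remains drop-in compatible with 12-column consumers.
#'
#' @param hits A [hit_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  m <- data.frame(hits$query, hits$subject, 0, 0, 0, 0, 0, 0, 0, 0,
                  format(hits$evalue, digits = 6),
                  format(hits$bitscore, digits = 6))
  write.table(m, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
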