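# Track and tree export: Newick via ape, BED tracks (0-based half-open) for
# per-ORF classifications, and plain TSV reports.

#' Write a tree in Newick format
#'
#' @param tree An `ape` `phylo` object with named leaves.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a per-ORF classification BED track
#'
#' Internal coordinates are 1-based inclusive (GenBank convention); BED
#' output is 0-based half-open. The name column carries
#' `<orf_id>|<class>` and the score column the differential clamped to
#' 0-1000.
#'
#' @param orfs An [orf_set()] carrying `start`/`end`/`strand` coordinates.
#' @param classes Character vector of per-ORF class labels (recycled against
#'   `orfs`), e.g. the `dba_class` column.
#' @param scores Numeric per-ORF scores (e.g. the trust differential).
#' @param path Output path.
#' @param chrom Replicon name for column 1 (default: the genome label).
#' @return `path`, invisibly.
#' @export
write_bed <- function(orfs, classes, scores, path, chrom = NULL) {
  if (is.null(orfs$start)) {
    stop("BED requested but ORFs lack coordinates: ",
         paste(head(orfs$orf_id, 5), collapse = ", "))
  }
  missing_coord <- is.na(orfs$start) | is.na(orfs$end)
  if (any(missing_coord)) {
    stop("BED requested but ORFs lack coordinates: ",
         paste(orfs$orf_id[missing_coord], collapse = ", "))
  }
  if (is.null(chrom)) chrom <- genome_id(orfs)
  bed <- data.frame(
    chrom = chrom,
    start = orfs$start - 1L,            # to 0-based half-open
    end = orfs$end,
    name = paste(orfs$orf_id, rep_len(classes, nrow(orfs)), sep = "|"),
    score = pmax(0, pmin(1000, round(rep_len(scores, nrow(orfs))))),
    strand = if (is.null(orfs$strand)) "+" else orfs$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write and read plain TSV reports
#'
#' Round-trip-safe TSV serialization for report data frames.
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly (`write_report_tsv`); the data frame
#'   (`read_report_tsv`).
#' @export
write_report_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a distance matrix as TSV with labels
#'
#' @param D Symmetric labelled matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(genome = rownames(D), D, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
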