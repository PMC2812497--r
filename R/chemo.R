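# Chemogenomic target intersection: three-way Venn of conserved (functional
# distribution), in-group-specific (differential homology) and curated
# metabolic gene sets; the central intersection is the candidate list.

#' Three-way target-set intersection
#'
#' Exact set algebra over three ORF-id sets from one reference genome's
#' namespace. All seven Venn regions are reported with lexicographically
#' sorted member lists; the central intersection is flagged as the
#' chemogenomic candidate set.
#'
#' @param fgd_set,dba_set,metabolic_set Character vectors of ORF ids.
#' @param reference Optional reference [orf_set()]; ids present in a set but
#'   absent from the reference trigger a warning (they are kept).
#' @return A list of class `VennReport`: `regions` (named list of member
#'   vectors: `fgd_only`, `dba_only`, `metabolic_only`, `fgd_dba`,
#'   `fgd_metabolic`, `dba_metabolic`, `all_three`), `counts` (named integer
#'   vector) and `candidates` (= `all_three`).
#' @export
intersect_targets <- function(fgd_set, dba_set, metabolic_set,
                              reference = NULL) {
  a <- unique(as.character(fgd_set))
  b <- unique(as.character(dba_set))
  c_ <- unique(as.character(metabolic_set))
  if (!is.null(reference)) {
    unknown <- setdiff(c(a, b, c_), reference$orf_id)
    if (length(unknown) > 0) {
      warning("ids not in reference ORF set (kept): ",
              paste(sort(unknown), collapse = ", "))
    }
  }
  u <- union(union(a, b), c_)
  in_a <- u %in% a; in_b <- u %in% b; in_c <- u %in% c_
  pick <- function(sel) sort(u[sel])
  regions <- list(
    fgd_only = pick(in_a & !in_b & !in_c),
    dba_only = pick(!in_a & in_b & !in_c),
    metabolic_only = pick(!in_a & !in_b & in_c),
    fgd_dba = pick(in_a & in_b & !in_c),
    fgd_metabolic = pick(in_a & !in_b & in_c),
    dba_metabolic = pick(!in_a & in_b & in_c),
    all_three = pick(in_a & in_b & in_c))
  structure(list(regions = regions,
                 counts = vapply(regions, length, integer(1)),
                 candidates = regions$all_three),
            class = "VennReport")
}

#' @export
print.VennReport <- function(x, ...) {
  cat("Three-way target intersection:\n")
  for (nm in names(x$counts)) cat(sprintf("  %-15s %d\n", nm, x$counts[nm]))
  cat(sprintf("  candidates (central): %d\n", length(x$candidates)))
  invisible(x)
}

#' Write a Venn report as TSV
#'
#' One row per region with count and comma-separated members.
#' @param report An [intersect_targets()] `VennReport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_venn_tsv <- function(report, path) {
  df <- data.frame(region = names(report$regions),
                   count = report$counts,
                   members = vapply(report$regions, paste,
                                    character(1), collapse = ","),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
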