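# Reverse-vaccinology candidate cascade: pool membrane/surface ORFs, remove
# non-in-group and special classes, refine by conservation, and split the
# survivors by transmembrane-helix count.

#' Assemble a per-ORF feature table
#'
#' The cascade consumes one row per ORF with the evidence columns it filters
#' on. Topology and signal-peptide columns normally come from imported
#' predictor tables ([read_tmhmm()], [read_signalp()]) and fall back to the
#' built-in predictors.
#'
#' @param orf_id Character vector of ORF ids.
#' @param tmh_count Integer count of predicted transmembrane helices (>= 0).
#' @param sp_flag Logical: signal peptide predicted (combined over models)?
#' @param top_hit_group `"ingroup"`, `"other"` or `"none"`: taxonomic group
#'   of the best out-group-database hit.
#' @param is_transposase,is_adhesin Logical special-class flags.
#' @param conservation_count Number of panel genomes with a qualifying hit.
#' @param localization Optional localization call
#'   (`cytoplasmic`/`membrane`/`surface`/`secreted`/`unknown`).
#' @return A `FeatureTable` data frame.
#' @export
feature_table <- function(orf_id, tmh_count, sp_flag,
                          top_hit_group = "ingroup",
                          is_transposase = FALSE, is_adhesin = FALSE,
                          conservation_count = 0L,
                          localization = "unknown") {
  tmh_count <- as.integer(tmh_count)
  if (any(tmh_count < 0)) stop("negative tmh_count")
  bad <- setdiff(unique(top_hit_group), c("ingroup", "other", "none"))
  if (length(bad)) stop("invalid top_hit_group: ", bad[1])
  structure(
    data.frame(orf_id = as.character(orf_id), tmh_count = tmh_count,
               sp_flag = as.logical(sp_flag),
               top_hit_group = rep_len(top_hit_group, length(orf_id)),
               is_transposase = rep_len(as.logical(is_transposase),
                                        length(orf_id)),
               is_adhesin = rep_len(as.logical(is_adhesin), length(orf_id)),
               conservation_count = rep_len(as.integer(conservation_count),
                                            length(orf_id)),
               localization = rep_len(localization, length(orf_id)),
               stringsAsFactors = FALSE),
    class = c("FeatureTable", "data.frame"))
}

#' Surface-target selection cascade
#'
#' Four audited steps over a [feature_table()]:
#' 1. *pool* — keep ORFs with at least one transmembrane helix or a signal
#'    peptide (membrane/surface location evidence);
#' 2. *exclusions* — drop ORFs whose top out-group hit is a non-in-group
#'    organism (`"other"`) or that have no homology at all (`"none"`), drop
#'    transposases, and set adhesin-like ORFs aside (they are handled as
#'    their own candidate class);
#' 3. *conservation* — keep ORFs with qualifying hits in at least
#'    `min_conservation` of the `panel_size` panel genomes (a configurable
#'    proxy for manual curation of function and conservation);
#' 4. *grouping* — split survivors into group A (<= 4 helices, amenable to
#'    heterologous expression) and group B (> 4 helices, peptide-vaccine
#'    route).
#'
#' @param features A [feature_table()].
#' @param min_conservation Minimum conservation count at step 3.
#' @param panel_size Number of genomes in the conservation panel (must be
#'   >= `min_conservation`).
#' @param tmh_group_cut Helix count above which an ORF goes to group B
#'   (default 4).
#' @return A list of class `CascadeReport`: `step_counts` (named integer
#'   vector: `input`, `pool`, `exclusions`, `conservation`), `group_A`,
#'   `group_B` (ORF ids), and `audit` (per-ORF data frame with `removed_at`
#'   and `reason`, `NA` for survivors).
#' @export
cascade_filter <- function(features, min_conservation, panel_size,
                           tmh_group_cut = 4L) {
  if (min_conservation > panel_size) {
    stop("min_conservation must be <= panel_size")
  }
  if (any(features$conservation_count > panel_size)) {
    stop("conservation_count exceeds panel_size")
  }
  n <- nrow(features)
  removed_at <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  alive <- rep(TRUE, n)

  drop <- alive & !(features$tmh_count >= 1 | features$sp_flag)
  removed_at[drop] <- "pool"
  reason[drop] <- "no transmembrane helix and no signal peptide"
  alive <- alive & !drop
  n_pool <- sum(alive)

  why <- character(n)
  why[features$top_hit_group == "other"] <- "top hit to non-in-group organism"
  why[features$top_hit_group == "none"] <- "no homology to reference database"
  why[features$is_transposase] <- "transposase"
  why[features$is_adhesin] <- "adhesin-like (handled separately)"
  drop <- alive & nzchar(why)
  removed_at[drop] <- "exclusions"
  reason[drop] <- why[drop]
  alive <- alive & !drop
  n_excl <- sum(alive)

  drop <- alive & features$conservation_count < min_conservation
  removed_at[drop] <- "conservation"
  reason[drop] <- sprintf("conserved in %d/%d genomes (< %d)",
                          features$conservation_count[drop], panel_size,
                          min_conservation)
  alive <- alive & !drop
  n_cons <- sum(alive)

  group_a <- features$orf_id[alive & features$tmh_count <= tmh_group_cut]
  group_b <- features$orf_id[alive & features$tmh_count > tmh_group_cut]

  structure(list(
    step_counts = c(input = n, pool = n_pool, exclusions = n_excl,
                    conservation = n_cons),
    group_A = group_a, group_B = group_b,
    audit = data.frame(orf_id = features$orf_id, removed_at = removed_at,
                       reason = reason, stringsAsFactors = FALSE)),
    class = "CascadeReport")
}

#' @export
print.CascadeReport <- function(x, ...) {
  cat("Surface-target cascade:",
      paste(sprintf("%s=%d", names(x$step_counts), x$step_counts),
            collapse = " -> "),
      sprintf("| group A: %d, group B: %d\n",
              length(x$group_A), length(x$group_B)))
  invisible(x)
}

#' Write a cascade report as TSV
#'
#' Serializes the per-ORF audit trail with a `#`-prefixed header of step
#' counts and group sizes.
#' @param report A [cascade_filter()] `CascadeReport`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cascade_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# step_counts: ",
           paste(sprintf("%s=%d", names(report$step_counts),
                         report$step_counts), collapse = ", ")),
    paste0("# group_A: ", length(report$group_A),
           "  group_B: ", length(report$group_B))), con)
  audit <- report$audit
  audit$group <- ifelse(audit$orf_id %in% report$group_A, "A",
                        ifelse(audit$orf_id %in% report$group_B, "B", ""))
  write.table(audit, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TMHMM short-format table
#'
#' One line per protein of whitespace-separated `key=value` fields, e.g.
#' `orf1 len=312 ExpAA=110.2 First60=2.1 PredHel=5 Topology=i12-31o46-65i...`.
#' Columns used: the name (first field), `PredHel` and `Topology`.
#'
#' @param path Input path.
#' @return Data frame with `orf_id`, `tmh_count` and `tmh_intervals` (list
#'   column of two-column matrices).
#' @export
read_tmhmm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parse_line <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    kv <- f[grepl("=", f, fixed = TRUE)]
    vals <- setNames(sub("^[^=]*=", "", kv), sub("=.*$", "", kv))
    topo <- vals[["Topology"]] %||% ""
    m <- gregexpr("(\\d+)-(\\d+)", topo)[[1]]
    iv <- if (m[1] > 0) {
      do.call(rbind, lapply(regmatches(topo, gregexpr("\\d+-\\d+", topo))[[1]],
                            function(p) as.integer(strsplit(p, "-")[[1]])))
    } else {
      matrix(integer(0), 0, 2)
    }
    list(orf_id = f[1],
         tmh_count = as.integer(vals[["PredHel"]] %||% nrow(iv)),
         tmh_intervals = iv)
  }
  rows <- lapply(lines, parse_line)
  out <- data.frame(orf_id = vapply(rows, `[[`, "", "orf_id"),
                    tmh_count = vapply(rows, `[[`, 1L, "tmh_count"),
                    stringsAsFactors = FALSE)
  out$tmh_intervals <- lapply(rows, `[[`, "tmh_intervals")
  out
}

#' Read a signal-peptide summary table
#'
#' Tab- or whitespace-separated columns `orf_id`, `model` (e.g. gram+,
#' gram-, euk), `decision` (Y/N) and optional `cleavage` position; `#` lines
#' are comments. Decisions are combined per ORF by OR over models.
#'
#' @param path Input path.
#' @return Data frame with `orf_id`, `sp_flag` (combined), `models_positive`.
#' @export
read_signalp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  f <- strsplit(trimws(lines), "\\s+")
  id <- vapply(f, `[[`, "", 1)
  dec <- toupper(vapply(f, `[[`, "", 3)) == "Y"
  data.frame(orf_id = unique(id),
             sp_flag = as.logical(tapply(dec, id, any)[unique(id)]),
             models_positive = as.integer(tapply(dec, id, sum)[unique(id)]),
             stringsAsFactors = FALSE)
}
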