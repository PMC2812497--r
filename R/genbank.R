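# GenBank-lite flat-file parser: LOCUS / FEATURES (CDS, tRNA, rRNA with
# /locus_tag, /product, /translation) / ORIGIN only. Full-dialect fidelity is
# deliberately out of scope; records must be terminated by "//".

read_genbank_lite <- function(path, genome_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^//\\s*$", lines))) {
    stop("truncated GenBank record (no terminating '//'): ", path)
  }
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L) stop("expected exactly one LOCUS line in ", path)
  locus_fields <- strsplit(trimws(lines[locus_i]), "\\s+")[[1]]
  locus_name <- locus_fields[2]
  if (is.null(genome_id)) genome_id <- locus_name

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1L) stop("expected one ORIGIN block in ", path)
  end_i <- grep("^//\\s*$", lines)[1]
  seq_lines <- lines[(origin_i + 1):(end_i - 1)]
  genome_seq <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))

  feat_i <- grep("^FEATURES", lines)
  if (length(feat_i) != 1L) stop("expected one FEATURES block in ", path)
  feat_lines <- lines[(feat_i + 1):(origin_i - 1)]

  # split the feature table into entries: a new entry starts in column 6
  starts <- grep("^ {5}\\S", feat_lines)
  features <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1] - 1L else length(feat_lines)
    entry <- feat_lines[from:to]
    key <- sub("^ {5}(\\S+).*", "\\1", entry[1])
    if (!key %in% c("CDS", "tRNA", "rRNA")) next
    loc <- sub("^ {5}\\S+\\s+", "", entry[1])
    quals <- parse_qualifiers(entry[-1])
    features[[length(features) + 1]] <-
      c(list(key = key, location = loc), quals)
  }

  cds <- Filter(function(f) f$key == "CDS", features)
  if (length(cds) == 0) stop("no CDS features found in ", path)
  rows <- lapply(cds, function(f) {
    loc <- parse_location(f$location)
    prot <- f[["translation"]]
    nt <- substr(genome_seq, loc$start, loc$end)
    if (loc$strand == "-") nt <- revcomp(nt)
    if (is.null(prot)) {
      prot <- translate_cds(nt)
    }
    list(orf_id = f[["locus_tag"]] %||% paste0("cds", loc$start),
         protein = prot, nucleotide = nt,
         start = loc$start, end = loc$end, strand = loc$strand,
         product = f[["product"]] %||% NA_character_)
  })
  os <- orf_set(genome_id,
                orf_id = vapply(rows, `[[`, "", "orf_id"),
                protein = vapply(rows, `[[`, "", "protein"),
                nucleotide = vapply(rows, `[[`, "", "nucleotide"),
                start = vapply(rows, `[[`, 1L, "start"),
                end = vapply(rows, `[[`, 1L, "end"),
                strand = vapply(rows, `[[`, "", "strand"),
                replicon_length = nchar(genome_seq))
  os$product <- vapply(rows, `[[`, "", "product")
  attr(os, "genome_seq") <- genome_seq
  os
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# qualifier lines: /name="value" possibly spanning several lines
parse_qualifiers <- function(lines) {
  txt <- paste(trimws(lines), collapse = "\n")
  pieces <- strsplit(txt, "\n/")[[1]]
  pieces <- sub("^/", "", pieces)
  quals <- list()
  for (p in pieces[nzchar(pieces)]) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) next
    name <- substr(p, 1, eq - 1)
    val <- gsub('"', "", substr(p, eq + 1, nchar(p)))
    if (name == "translation") val <- gsub("\\s", "", val)
    else val <- gsub("\n", " ", val)
    quals[[name]] <- val
  }
  quals
}

parse_location <- function(loc) {
  loc <- gsub("[<>]", "", trimws(loc))
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  m <- regmatches(loc, regexec("^(\\d+)\\.\\.(\\d+)$", loc))[[1]]
  if (length(m) != 3) stop("unsupported feature location: ", loc)
  list(start = as.integer(m[2]), end = as.integer(m[3]), strand = strand)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# standard-code translation of a CDS span; trailing stop removed
translate_cds <- function(nt) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}
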