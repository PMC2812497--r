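#' ORF set: one genome's predicted proteome
#'
#' An `OrfSet` holds the predicted protein-coding ORFs of a single genome:
#' unique ORF identifiers, amino-acid sequences, and optionally the nucleotide
#' sequences and 1-based inclusive coordinates on the source replicon.
#'
#' @param genome_id Short genome label.
#' @param orf_id Character vector of unique ORF identifiers.
#' @param protein Character vector of amino-acid sequences (20 standard
#'   residues plus `X`; `B`, `Z` and `U` are mapped to `X` with a warning).
#' @param nucleotide Optional character vector of nucleotide sequences.
#' @param start,end,strand Optional 1-based inclusive coordinates and strand
#'   (`"+"`/`"-"`) on the source replicon.
#' @param replicon_length Optional replicon length used to validate
#'   coordinates.
#' @return An object of class `OrfSet`: a data frame with columns `orf_id`,
#'   `protein` and, when supplied, `nucleotide`, `start`, `end`, `strand`;
#'   the genome label is stored in attribute `genome_id`.
#' @export
orf_set <- function(genome_id, orf_id, protein, nucleotide = NULL,
                    start = NULL, end = NULL, strand = NULL,
                    replicon_length = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  orf_id <- as.character(orf_id)
  protein <- toupper(as.character(protein))
  if (length(orf_id) != length(protein)) {
    stop("orf_id and protein must have the same length")
  }
  dup <- orf_id[duplicated(orf_id)]
  if (length(dup) > 0) {
    stop("duplicate ORF id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(!nzchar(protein))) {
    stop("empty protein sequence for ORF(s): ",
         paste(orf_id[!nzchar(protein)], collapse = ", "))
  }
  protein <- clean_protein(protein, orf_id)
  df <- data.frame(orf_id = orf_id, protein = protein,
                   stringsAsFactors = FALSE)
  if (!is.null(nucleotide)) df$nucleotide <- toupper(as.character(nucleotide))
  if (!is.null(start)) {
    stopifnot(!is.null(end))
    start <- as.integer(start); end <- as.integer(end)
    bad <- which(!(start >= 1L & start <= end))
    if (length(bad) > 0) {
      stop("invalid coordinates (need 1 <= start <= end) for ORF(s): ",
           paste(orf_id[bad], collapse = ", "))
    }
    if (!is.null(replicon_length) && any(end > replicon_length)) {
      stop("ORF end beyond replicon length for: ",
           paste(orf_id[end > replicon_length], collapse = ", "))
    }
    df$start <- start
    df$end <- end
    df$strand <- if (is.null(strand)) "+" else as.character(strand)
  }
  structure(df, genome_id = genome_id, class = c("OrfSet", "data.frame"))
}

# Validate the amino-acid alphabet; map B/Z/U to X (warn), reject anything
# else with the offending position.
clean_protein <- function(protein, orf_id) {
  mapped <- chartr("BZU", "XXX", protein)
  if (!identical(mapped, protein)) {
    warning("ambiguous residues B/Z/U mapped to X in ORF(s): ",
            paste(orf_id[mapped != protein], collapse = ", "))
  }
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", mapped)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("illegal residue '%s' at position %d of ORF %s",
                 substr(mapped[i], bad[i], bad[i]), bad[i], orf_id[i]))
  }
  mapped
}

#' @export
print.OrfSet <- function(x, ...) {
  cat(sprintf("OrfSet '%s': %d ORFs (protein lengths %d-%d)\n",
              attr(x, "genome_id"), nrow(x),
              if (nrow(x)) min(nchar(x$protein)) else 0L,
              if (nrow(x)) max(nchar(x$protein)) else 0L))
  invisible(x)
}

#' Genome label of an OrfSet
#' @param x An `OrfSet`.
#' @return The genome label.
#' @export
genome_id <- function(x) attr(x, "genome_id")

#' Read sequences from FASTA or GenBank-lite files
#'
#' @param path Path to the input file.
#' @param kind One of `"protein_fasta"` (returns an [orf_set()]),
#'   `"nucleotide_fasta"` (returns a named character vector of sequences), or
#'   `"genbank_lite"` (returns an `OrfSet` of CDS features keyed by locus_tag,
#'   with the replicon sequence in attribute `genome_seq`).
#' @param genome_id Genome label; defaults to the file name without extension
#'   (FASTA) or the LOCUS name (GenBank).
#' @return See `kind`.
#' @export
read_sequences <- function(path,
                           kind = c("protein_fasta", "nucleotide_fasta",
                                    "genbank_lite"),
                           genome_id = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genome_id)) {
    genome_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (kind == "genbank_lite") {
    return(read_genbank_lite(path, genome_id = genome_id))
  }
  set <- if (kind == "protein_fasta") {
    Biostrings::readAAStringSet(path)
  } else {
    Biostrings::readDNAStringSet(path)
  }
  nm <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(nm))) stop("empty FASTA header in ", path)
  if (kind == "nucleotide_fasta") {
    return(setNames(as.character(set), nm))
  }
  orf_set(genome_id, nm, as.character(set))
}

#' Write an OrfSet (or any named sequences) as FASTA
#'
#' @param x An `OrfSet`, or a named character vector of sequences.
#' @param path Output path.
#' @param what For an `OrfSet`, which sequence column to write.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, what = c("protein", "nucleotide")) {
  if (inherits(x, "OrfSet")) {
    what <- match.arg(what)
    seqs <- setNames(x[[what]], x$orf_id)
  } else {
    seqs <- x
  }
  wrapped <- vapply(seqs, function(s) {
    paste(substring(s, seq(1, nchar(s), 60),
                    pmin(seq(1, nchar(s), 60) + 59, nchar(s))),
          collapse = "\n")
  }, character(1))
  writeLines(paste0(">", names(seqs), "\n", wrapped), path)
  invisible(path)
}
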