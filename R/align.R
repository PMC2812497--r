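#' Alignment parameters
#'
#' Scoring parameters for the built-in local protein alignment used when no
#' external homology search results are supplied. Raw Smith-Waterman scores
#' are converted to bit scores and e-values with the gapped Karlin-Altschul
#' parameters for BLOSUM62 with gap open 11 / extend 1
#' (lambda = 0.267, K = 0.041):
#' \deqn{S' = (\lambda S - \ln K)/\ln 2, \qquad E = m n \, 2^{-S'}}
#' where `m`, `n` are the query and subject lengths. Ambiguous residue `X`
#' scores 0 against everything.
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is bundled) or a
#'   numeric matrix with amino-acid dimnames.
#' @param gap_open,gap_extend Positive gap costs; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param lambda,K Gapped Karlin-Altschul parameters.
#' @param evalue_ceiling Hits with e-value above this are not reported.
#' @param max_len Sequences longer than this are rejected (use a dedicated
#'   external search tool for such inputs).
#' @return An `AlignParams` list.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                         lambda = 0.267, K = 0.041, evalue_ceiling = 10,
                         max_len = 50000) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0, lambda > 0, K > 0)
  if (is.character(matrix)) {
    if (matrix != "BLOSUM62") stop("only BLOSUM62 is bundled")
    matrix <- blosum62x()
  }
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 evalue_ceiling = evalue_ceiling, max_len = max_len),
            class = "AlignParams")
}

# BLOSUM62 restricted to the 20 amino acids + X, with X scoring 0 against
# everything (ambiguity carries no signal either way).
blosum62x <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
  m <- e$BLOSUM62[aa, aa]
  m["X", ] <- 0
  m[, "X"] <- 0
  m
}

karlin_bits <- function(raw, p) (p$lambda * raw - log(p$K)) / log(2)
karlin_evalue <- function(bits, m, n) m * n * 2^(-bits)

#' Local pairwise protein alignment
#'
#' Smith-Waterman local alignment with affine gaps (via
#' `Biostrings::pairwiseAlignment`), reported with Karlin-Altschul bit score
#' and e-value. A raw score of 0 means no reportable hit.
#'
#' @param a,b Protein sequences (character scalars).
#' @param params An [align_params()] object.
#' @return A list of class `Alignment`: `raw_score`, `bit_score`, `evalue`,
#'   `q_start`, `q_end`, `s_start`, `s_end` (alignment coordinates are `NA`
#'   when there is no hit).
#' @export
align_pair <- function(a, b, params = align_params()) {
  check_align_input(a, params)
  check_align_input(b, params)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = params$matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  raw <- max(0, Biostrings::score(pa))
  bits <- karlin_bits(raw, params)
  ev <- karlin_evalue(bits, nchar(a), nchar(b))
  coords <- if (raw > 0) {
    c(q_start = Biostrings::start(Biostrings::pattern(pa)),
      q_end = Biostrings::end(Biostrings::pattern(pa)),
      s_start = Biostrings::start(Biostrings::subject(pa)),
      s_end = Biostrings::end(Biostrings::subject(pa)))
  } else {
    c(q_start = NA_integer_, q_end = NA_integer_,
      s_start = NA_integer_, s_end = NA_integer_)
  }
  structure(c(list(raw_score = raw, bit_score = bits, evalue = ev),
              as.list(coords)),
            class = "Alignment")
}

check_align_input <- function(s, params) {
  if (!is.character(s) || length(s) != 1L || !nzchar(s)) {
    stop("sequences must be non-empty character scalars")
  }
  if (nchar(s) > params$max_len) {
    stop("sequence longer than ", params$max_len,
         " residues; use an external search tool")
  }
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", s)) {
    stop("invalid residue in sequence")
  }
}

#' Self-alignment bit scores of an ORF set
#'
#' The optimal local self-alignment of a sequence under BLOSUM62 is the full
#' ungapped diagonal (every diagonal entry is positive), so self bit scores
#' are computed directly from the substitution-matrix diagonal.
#'
#' @param orfs An [orf_set()].
#' @param params An [align_params()] object.
#' @return Named numeric vector of self bit scores.
#' @export
self_bit_scores <- function(orfs, params = align_params()) {
  raw <- vapply(strsplit(orfs$protein, ""), function(res) {
    sum(params$matrix[cbind(res, res)])
  }, numeric(1))
  setNames(karlin_bits(raw, params), orfs$orf_id)
}

# Distinct shared k-mer counts between two proteomes, as a dense
# queries x subjects matrix (via sparse incidence-matrix crossproduct).
shared_kmer_counts <- function(qseqs, sseqs, k = 5) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  qk <- lapply(qseqs, kmers)
  sk <- lapply(sseqs, kmers)
  vocab <- unique(c(unlist(qk), unlist(sk)))
  inc <- function(kl) {
    Matrix::sparseMatrix(
      i = rep(seq_along(kl), lengths(kl)),
      j = match(unlist(kl), vocab),
      x = 1, dims = c(length(kl), length(vocab)))
  }
  as.matrix(inc(qk) %*% Matrix::t(inc(sk)))
}

#' Best hits of each query ORF against a target ORF set
#'
#' Aligns every query against every target and keeps, per query, the single
#' best subject with e-value at or below the ceiling (lowest e-value, ties by
#' highest bit score then lexicographic subject id). Queries without a
#' qualifying hit are absent from the result.
#'
#' @param queries,targets [orf_set()] objects.
#' @param params An [align_params()] object.
#' @param prefilter If `TRUE`, pairs sharing fewer than `min_shared_kmers`
#'   distinct `prefilter_k`-mers are skipped without alignment. Off by
#'   default, in which case results are exactly the exhaustive all-pairs
#'   reduction.
#' @param min_shared_kmers Seed-count threshold for the prefilter.
#' @param prefilter_k Seed word length (default 5; long enough that random
#'   pairs of full-length proteins share almost no seeds, while homologs at
#'   the divergence levels of interest share many).
#' @return A [hit_table()] with `database` set to the target genome label.
#' @export
best_hits <- function(queries, targets, params = align_params(),
                      prefilter = FALSE, min_shared_kmers = 2,
                      prefilter_k = 5) {
  if (nrow(targets) == 0) {
    warning("empty target set; returning empty hit table")
    return(hit_table())
  }
  cand <- if (prefilter) {
    shared_kmer_counts(queries$protein, targets$protein,
                       k = prefilter_k) >= min_shared_kmers
  } else {
    matrix(TRUE, nrow(queries), nrow(targets))
  }
  qlen <- nchar(queries$protein)
  tlen <- nchar(targets$protein)
  tset <- Biostrings::AAStringSet(setNames(targets$protein, targets$orf_id))
  rows <- vector("list", nrow(targets))
  for (j in seq_len(nrow(targets))) {
    qi <- which(cand[, j])
    if (length(qi) == 0) next
    raw <- pmax(0, Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(queries$protein[qi]), tset[[j]],
      type = "local", substitutionMatrix = params$matrix,
      gapOpening = params$gap_open, gapExtension = params$gap_extend,
      scoreOnly = TRUE))
    bits <- karlin_bits(raw, params)
    ev <- karlin_evalue(bits, qlen[qi], tlen[j])
    ok <- raw > 0 & ev <= params$evalue_ceiling
    if (!any(ok)) next
    rows[[j]] <- data.frame(
      query = queries$orf_id[qi][ok],
      query_genome = genome_id(queries),
      subject = targets$orf_id[j],
      database = genome_id(targets),
      evalue = ev[ok], bitscore = bits[ok],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) return(hit_table())
  all <- do.call(rbind, rows)
  reduce_best_hits(structure(all, class = c("HitTable", "data.frame")))
}
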