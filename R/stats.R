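# Nucleotide-level genome statistics: windowed GC content and GC skew with
# cumulative-skew replication-origin prediction, codon adaptation index, and
# a composite horizontal-gene-transfer flag.

#' Windowed GC / GC-skew composition profile
#'
#' Sliding windows (start positions every `step` bases) over a replicon,
#' reporting per-window GC fraction and GC skew `(G - C) / (G + C)`, the
#' cumulative skew series, and the replication origin/terminus candidates at
#' the global minimum/maximum of the cumulative series (the polarity
#' switches). Circular replicons wrap the final windows; in linear mode only
#' full windows are scored.
#'
#' @param seq Nucleotide sequence (character scalar, alphabet ACGTN).
#' @param window Window width in bases (default 5000).
#' @param step Distance between window starts (default 500; must be
#'   <= `window`).
#' @param circular Wrap windows around the origin? Default `TRUE`.
#' @return A data frame of class `CompositionProfile` with columns
#'   `window_start` (1-based), `gc`, `skew`, `cum_skew`; attributes
#'   `oriC_candidate` and `terminus_candidate` hold the window starts at the
#'   cumulative-skew minimum and maximum.
#' @export
composition_profile <- function(seq, window = 5000, step = 500,
                                circular = TRUE) {
  if (window <= 0 || window < step) stop("need window >= step > 0")
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) stop("alphabet must be ACGTN")
  L <- nchar(seq)
  if (L < window) stop("sequence shorter than one window")
  starts <- if (circular) seq(1L, L, by = step) else
    seq(1L, L - window + 1L, by = step)
  padded <- if (circular) paste0(seq, substr(seq, 1, window - 1)) else seq
  v <- Biostrings::Views(Biostrings::DNAString(padded),
                         start = starts, width = window)
  freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
  gcsum <- freq[, "G"] + freq[, "C"]
  atgc <- rowSums(freq)
  gc <- ifelse(atgc > 0, gcsum / atgc, 0)
  skew <- ifelse(gcsum > 0, (freq[, "G"] - freq[, "C"]) / gcsum, 0)
  cum <- cumsum(skew)
  out <- data.frame(window_start = starts, gc = gc, skew = skew,
                    cum_skew = cum)
  attr(out, "oriC_candidate") <- starts[which.min(cum)]
  attr(out, "terminus_candidate") <- starts[which.max(cum)]
  class(out) <- c("CompositionProfile", "data.frame")
  out
}

#' Build a codon relative-adaptiveness model
#'
#' Relative adaptiveness `w` of each sense codon: its frequency in a
#' reference gene set (canonically highly expressed genes such as ribosomal
#' proteins) divided by the frequency of the most-used synonymous codon for
#' the same amino acid. Codons unobserved in the reference receive a
#' pseudo-floor of 0.01.
#'
#' @param genes Character vector of in-frame nucleotide coding sequences.
#' @return Named numeric vector of class `CaiModel` over the 61 sense codons.
#' @export
build_cai_model <- function(genes) {
  codons <- unlist(lapply(toupper(genes), split_codons))
  gc_tab <- Biostrings::GENETIC_CODE
  sense <- names(gc_tab)[gc_tab != "*"]
  counts <- table(factor(codons[codons %in% sense], levels = sense))
  w <- setNames(numeric(length(sense)), sense)
  for (aa in unique(gc_tab[sense])) {
    fam <- sense[gc_tab[sense] == aa]
    mx <- max(counts[fam])
    w[fam] <- if (mx > 0) as.numeric(counts[fam]) / mx else 1
  }
  w[w == 0] <- 0.01
  structure(w, class = "CaiModel")
}

split_codons <- function(gene) {
  n <- nchar(gene)
  if (n %% 3 != 0) stop("gene length not divisible by 3")
  substring(gene, seq(1, n, 3), seq(3, n, 3))
}

#' Codon adaptation index of a gene
#'
#' Geometric mean of relative adaptiveness over the gene's codons, excluding
#' Met (ATG), Trp (TGG) and stop codons (single-codon families carry no
#' choice). Internal stop codons are an error; a terminal stop is allowed.
#'
#' @param gene In-frame nucleotide coding sequence.
#' @param model A [build_cai_model()] `CaiModel`.
#' @return CAI in (0, 1].
#' @export
compute_cai <- function(gene, model) {
  codons <- split_codons(toupper(gene))
  gc_tab <- Biostrings::GENETIC_CODE
  is_stop <- gc_tab[codons] == "*"
  if (any(is_stop[-length(is_stop)])) {
    stop("internal stop codon at codon ",
         which(is_stop[-length(is_stop)])[1])
  }
  codons <- codons[!is_stop]
  scored <- codons[!codons %in% c("ATG", "TGG")]
  if (length(scored) == 0) stop("no scorable codons")
  exp(mean(log(model[scored])))
}

#' Composite horizontal-gene-transfer flag
#'
#' Flags ORFs whose nucleotide composition and codon usage both deviate from
#' the genome norm *and* whose best out-group hit is to a non-in-group
#' organism: `|gc_z| >= z_cut` (robustly standardized GC deviation across
#' ORFs: centred on the median and scaled by the MAD, so that the foreign
#' genes being screened for cannot inflate the scale estimate),
#' CAI percentile <= `cai_q`, and `top_hit_group == "other"`.
#'
#' @param orf_stats Data frame with columns `orf_id`, `gc` (per-ORF GC
#'   fraction), `cai`, `top_hit_group`; at least 20 rows so the genome GC
#'   distribution is estimable.
#' @param z_cut GC z-score threshold (default 2).
#' @param cai_q CAI percentile threshold (default 0.25).
#' @return `orf_stats` augmented with `gc_z`, `cai_percentile`, `flagged`.
#' @export
flag_hgt <- function(orf_stats, z_cut = 2.0, cai_q = 0.25) {
  if (nrow(orf_stats) < 20) stop("need >= 20 ORFs to estimate the GC norm")
  gc_z <- (orf_stats$gc - stats::median(orf_stats$gc)) /
    stats::mad(orf_stats$gc)
  cai_pct <- ecdf(orf_stats$cai)(orf_stats$cai)
  out <- orf_stats
  out$gc_z <- gc_z
  out$cai_percentile <- cai_pct
  out$flagged <- abs(gc_z) >= z_cut & cai_pct <= cai_q &
    orf_stats$top_hit_group == "other"
  out
}

#' Per-sequence GC fraction
#'
#' @param seqs Character vector of nucleotide sequences.
#' @return Numeric vector of GC fractions (N bases excluded).
#' @export
gc_fraction <- function(seqs) {
  vapply(toupper(seqs), function(s) {
    f <- Biostrings::letterFrequency(Biostrings::DNAString(s),
                                     c("A", "C", "G", "T"))
    (f[["C"]] + f[["G"]]) / max(1, sum(f))
  }, numeric(1), USE.NAMES = FALSE)
}
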