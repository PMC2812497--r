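# Differential homology analysis: best-hit e-values against an in-group and
# an out-group protein database are discretized into integer trust levels and
# each ORF is classified by the differential delta = T_out - T_in.

#' E-value trust level
#'
#' Discretizes a best-hit e-value into an integer trust level:
#' `floor(-log10 e)` capped at `t_cap`; e-values above `e_floor` (or missing
#' hits) give 0; an e-value of exactly 0 gives the cap.
#'
#' @param evalue Numeric vector of e-values (`NA` = no hit).
#' @param e_floor E-values above this carry no trust (default 1e-3).
#' @param t_cap Upper bound on the trust level (default 200).
#' @return Integer vector of trust levels in \[0, t_cap\].
#' @export
trust_level <- function(evalue, e_floor = 1e-3, t_cap = 200L) {
  if (any(evalue < 0, na.rm = TRUE)) stop("negative e-value")
  t <- integer(length(evalue))
  zero <- !is.na(evalue) & evalue == 0
  scored <- !is.na(evalue) & evalue > 0 & evalue <= e_floor
  t[zero] <- as.integer(t_cap)
  t[scored] <- pmin(as.integer(t_cap),
                    as.integer(floor(-log10(evalue[scored]))))
  t
}

#' Trust profile from two best-hit tables
#'
#' When the searched databases pool several genomes, pairwise e-values
#' understate how often a weak alignment arises by chance in the whole
#' database. Supplying `query_lengths` and the database sizes recomputes each
#' hit's e-value on the database scale, `E = m * N * 2^(-S')` with `N` the
#' total database residue count — the statistic a database search reports.
#' Without them, the e-values in the hit tables are used as given.
#'
#' @param orf_ids Character vector of the reference genome's ORF ids.
#' @param hits_in,hits_out Reduced [hit_table()]s of the reference ORFs
#'   against the in-group and out-group databases (pooled; only the lowest
#'   e-value per query is used).
#' @param e_floor,t_cap Passed to [trust_level()].
#' @param query_lengths Optional named vector of query protein lengths.
#' @param db_in,db_out Optional total residue counts of the two databases.
#' @return Data frame `TrustProfile` with columns `orf_id`, `T_in`, `T_out`.
#' @export
trust_profile <- function(orf_ids, hits_in, hits_out,
                          e_floor = 1e-3, t_cap = 200L,
                          query_lengths = NULL, db_in = NULL,
                          db_out = NULL) {
  best_ev <- function(ht, db_size) {
    if (nrow(ht) == 0) return(setNames(numeric(0), character(0)))
    ev <- ht$evalue
    if (!is.null(db_size) && !is.null(query_lengths)) {
      ev <- as.numeric(query_lengths[ht$query]) * db_size *
        2^(-ht$bitscore)
    }
    tapply(ev, ht$query, min)
  }
  ev_in <- best_ev(hits_in, db_in)[orf_ids]
  ev_out <- best_ev(hits_out, db_out)[orf_ids]
  data.frame(orf_id = orf_ids,
             T_in = trust_level(as.numeric(ev_in), e_floor, t_cap),
             T_out = trust_level(as.numeric(ev_out), e_floor, t_cap),
             stringsAsFactors = FALSE)
}

#' Classify ORFs by their trust-level differential
#'
#' Computes `delta = T_out - T_in` per ORF and assigns a class:
#' * `ingroup_specific` — `T_in >= tau_present` and `T_out < tau_absent`
#'   (found in the in-group, absent from the out-group);
#' * `outgroup_only` — `T_out >= tau_present` and `T_in < tau_absent`;
#' * `orphan` — both below `tau_absent`;
#' * `shared` — both at or above `tau_present`, and all remaining borderline
#'   profiles (conservative default).
#'
#' @param profile A [trust_profile()] data frame (columns `orf_id`, `T_in`,
#'   `T_out`).
#' @param tau_present Trust level at or above which a gene counts as present
#'   (default 10).
#' @param tau_absent Trust level below which a gene counts as absent
#'   (default 3); must be `< tau_present`.
#' @return Data frame `DbaResult` with columns `orf_id`, `T_in`, `T_out`,
#'   `delta`, `dba_class`.
#' @export
dba_classify <- function(profile, tau_present = 10L, tau_absent = 3L) {
  if (!tau_absent < tau_present) stop("tau_absent must be < tau_present")
  T_in <- profile$T_in
  T_out <- profile$T_out
  cls <- rep("shared", nrow(profile))
  cls[T_in >= tau_present & T_out < tau_absent] <- "ingroup_specific"
  cls[T_out >= tau_present & T_in < tau_absent] <- "outgroup_only"
  cls[T_in < tau_absent & T_out < tau_absent] <- "orphan"
  data.frame(orf_id = profile$orf_id, T_in = T_in, T_out = T_out,
             delta = T_out - T_in, dba_class = cls,
             stringsAsFactors = FALSE)
}

#' Write a per-ORF differential-homology TSV
#'
#' @param result A [dba_classify()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dba_tsv <- function(result, path) {
  write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
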