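# Surface-protein prediction primitives: hydropathy-based transmembrane-helix
# prediction, an n/h/c-region signal-peptide heuristic, and extraction of
# extracellular loop peptides. These are deliberately lightweight stand-ins
# for full HMM/NN predictors; the cascade preferentially consumes imported
# prediction tables and falls back to these.

#' Kyte-Doolittle hydropathy scale
#'
#' Standard per-residue hydropathy values; `X` is scored 0 (no information).
#' @return Named numeric vector over the 20 amino acids plus `X`.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2, X = 0)
}

hydropathy_profile <- function(res, window) {
  kd <- kyte_doolittle()
  if (any(!res %in% names(kd))) {
    stop("invalid residue: ", res[!res %in% names(kd)][1])
  }
  h <- kd[res]
  as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
}

#' Predict transmembrane helices by sliding-window hydropathy
#'
#' Mean Kyte-Doolittle hydropathy over sliding windows, assigned to the
#' window centre; maximal runs of at least `min_run` centres at or above
#' `threshold` become helices, constrained to the canonical 15-35 residue
#' length band (short runs are widened symmetrically to 15, long runs split
#' evenly). A run of `min_run` centres corresponds to a hydrophobic stretch
#' of about `min_run + window - 10` residues, the physical minimum for a
#' membrane-spanning helix; shorter excursions above the threshold are
#' treated as noise. Membrane
#' orientation follows the positive-inside rule: lysine/arginine residues in
#' the 15 loop positions flanking each helix are summed over the two
#' alternating loop parities, and the richer side faces inside (tie: the
#' N-terminus is inside).
#'
#' @param seq Protein sequence (character scalar).
#' @param window Sliding-window width in residues (default 19).
#' @param threshold Mean-hydropathy threshold for membrane windows
#'   (default 1.6).
#' @param min_run Minimum number of consecutive qualifying window centres
#'   for a helix call (default 9).
#' @return A list of class `Topology`: `tmh_count`, `tmh_intervals`
#'   (two-column matrix of residue intervals), `orientation`
#'   (`"N_in"`/`"N_out"`), and `loops` (data frame `start`, `end`, `side`
#'   with `side` in `inside`/`outside`; terminal tails count as loops).
#' @export
predict_tmh <- function(seq, window = 19, threshold = 1.6, min_run = 9) {
  res <- strsplit(toupper(seq), "")[[1]]
  L <- length(res)
  if (any(!res %in% names(kyte_doolittle()))) {
    stop("invalid residue: ", res[!res %in% names(kyte_doolittle())][1])
  }
  if (L < window) {
    return(new_topology(matrix(numeric(0), 0, 2), "N_in", L))
  }
  prof <- hydropathy_profile(res, window)
  centers <- which(!is.na(prof) & prof >= threshold)
  iv <- runs_to_intervals(centers)
  iv <- iv[iv[, 2] - iv[, 1] + 1 >= min_run, , drop = FALSE]
  iv <- enforce_helix_bounds(iv, L, min_len = 15, max_len = 35)
  orientation <- orient_positive_inside(res, iv)
  new_topology(iv, orientation, L)
}

runs_to_intervals <- function(pos) {
  if (length(pos) == 0) return(matrix(numeric(0), 0, 2))
  brk <- c(0, which(diff(pos) > 1), length(pos))
  t(vapply(seq_len(length(brk) - 1), function(k) {
    c(pos[brk[k] + 1], pos[brk[k + 1]])
  }, numeric(2)))
}

enforce_helix_bounds <- function(iv, L, min_len = 15, max_len = 35) {
  out <- list()
  for (k in seq_len(nrow(iv))) {
    a <- iv[k, 1]; b <- iv[k, 2]
    len <- b - a + 1
    if (len < min_len) {
      pad <- min_len - len
      a <- max(1, a - ceiling(pad / 2))
      b <- min(L, a + min_len - 1)
      a <- max(1, b - min_len + 1)
      out[[length(out) + 1]] <- c(a, b)
    } else if (len > max_len) {
      npieces <- ceiling(len / max_len)
      cuts <- round(seq(a - 1, b, length.out = npieces + 1))
      for (p in seq_len(npieces)) {
        out[[length(out) + 1]] <- c(cuts[p] + 1, cuts[p + 1])
      }
    } else {
      out[[length(out) + 1]] <- c(a, b)
    }
  }
  if (length(out) == 0) return(matrix(numeric(0), 0, 2))
  m <- do.call(rbind, out)
  m <- m[order(m[, 1]), , drop = FALSE]
  # widening two nearby short runs can make them touch; clip to keep the
  # intervals disjoint
  for (k in seq_len(nrow(m))[-1]) {
    if (m[k, 1] <= m[k - 1, 2]) m[k, 1] <- m[k - 1, 2] + 1
  }
  m[m[, 1] <= m[, 2], , drop = FALSE]
}

loop_intervals <- function(iv, L) {
  # loops between/around helices, N- to C-terminal; may be empty
  bounds <- rbind(c(0, 0), iv, c(L + 1, L + 1))
  loops <- list()
  for (k in seq_len(nrow(bounds) - 1)) {
    a <- bounds[k, 2] + 1
    b <- bounds[k + 1, 1] - 1
    loops[[k]] <- c(a, b)  # may be degenerate (a > b) for abutting helices
  }
  do.call(rbind, loops)
}

orient_positive_inside <- function(res, iv) {
  if (nrow(iv) == 0) return("N_in")
  L <- length(res)
  loops <- loop_intervals(iv, L)
  kr <- res %in% c("K", "R")
  side_count <- c(0, 0)  # parity 1 (N-side), parity 2
  for (k in seq_len(nrow(loops))) {
    a <- loops[k, 1]; b <- loops[k, 2]
    if (a > b) next
    # only residues within 15 of a helix boundary carry the signal
    near <- logical(b - a + 1)
    if (k > 1) near[seq_len(min(15, b - a + 1))] <- TRUE   # after helix k-1
    if (k <= nrow(iv)) {                                   # before helix k
      near[seq(to = b - a + 1, length.out = min(15, b - a + 1))] <- TRUE
    }
    cnt <- sum(kr[a:b][near])
    parity <- 2 - k %% 2
    side_count[parity] <- side_count[parity] + cnt
  }
  if (side_count[1] >= side_count[2]) "N_in" else "N_out"
}

new_topology <- function(iv, orientation, L) {
  colnames(iv) <- c("start", "end")
  loops <- loop_intervals(if (nrow(iv)) iv else matrix(numeric(0), 0, 2), L)
  loop_df <- if (is.null(loops)) {
    data.frame(start = 1, end = L, side = "inside")
  } else {
    keep <- loops[, 1] <= loops[, 2]
    parity <- (seq_len(nrow(loops)) %% 2 == 1)  # TRUE = N-terminal parity
    side <- ifelse(parity == (orientation == "N_in"), "inside", "outside")
    data.frame(start = loops[keep, 1], end = loops[keep, 2],
               side = side[keep], stringsAsFactors = FALSE)
  }
  structure(list(tmh_count = nrow(iv), tmh_intervals = iv,
                 orientation = orientation, loops = loop_df,
                 length = L),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat(sprintf("Topology: %d TMH, orientation %s\n", x$tmh_count,
              x$orientation))
  invisible(x)
}

#' Heuristic signal-peptide prediction
#'
#' Tripartite n/h/c-region test within the first 45 residues: (n) at least
#' one K/R in residues 1-5; (h) an 8-residue window within residues 4-30 with
#' mean Kyte-Doolittle hydropathy at or above the stringency threshold
#' (strict 1.8, default 1.5, loose 1.2); (c) an A-x-A motif whose second A
#' lies at residue 16-40, the residue after which is reported as the cleavage
#' site. Passing several stringencies combines them by OR (positive under any
#' requested preset), mirroring the practice of merging multiple
#' signal-peptide model outputs.
#'
#' @param seq Protein sequence; sequences shorter than 25 residues are
#'   negative.
#' @param stringency Character vector from `"strict"`, `"default"`,
#'   `"loose"`.
#' @return List with `sp_flag` (logical) and `cleavage` (position of the
#'   first residue of the mature protein, or `NA`).
#' @export
predict_signal_peptide <- function(seq, stringency = "default") {
  thr <- c(strict = 1.8, default = 1.5, loose = 1.2)
  stringency <- match.arg(stringency, names(thr), several.ok = TRUE)
  res <- strsplit(toupper(seq), "")[[1]]
  L <- length(res)
  if (L < 25) return(list(sp_flag = FALSE, cleavage = NA_integer_))
  kd <- kyte_doolittle()
  if (any(!res %in% names(kd))) {
    stop("invalid residue: ", res[!res %in% names(kd)][1])
  }
  n_ok <- any(res[1:5] %in% c("K", "R"))
  h_end <- min(30, L)
  h <- kd[res[4:h_end]]
  h_max <- if (length(h) >= 8) {
    max(as.numeric(stats::filter(h, rep(1 / 8, 8), sides = 2)), na.rm = TRUE)
  } else {
    -Inf
  }
  c_hi <- min(40, L)
  second_a <- which(res == "A" & seq_along(res) >= 16 & seq_along(res) <= c_hi)
  second_a <- second_a[second_a - 2 >= 1 & res[pmax(second_a - 2, 1)] == "A"]
  c_ok <- length(second_a) > 0
  flag <- n_ok && c_ok && any(h_max >= thr[stringency])
  list(sp_flag = flag,
       cleavage = if (flag) second_a[1] + 1L else NA_integer_)
}

#' Extract candidate surface-loop peptides
#'
#' Returns every loop on the outside face of the membrane (per the topology's
#' orientation) whose length is within bounds; terminal tails count as loops.
#'
#' @param seq Protein sequence.
#' @param topology A [predict_tmh()] `Topology` for `seq`.
#' @param L_min,L_max Loop-length bounds in residues (defaults 8 and 40).
#' @return Data frame with `start`, `end`, `peptide`.
#' @export
extract_surface_loops <- function(seq, topology, L_min = 8, L_max = 40) {
  stopifnot(inherits(topology, "Topology"))
  lp <- topology$loops
  lp <- lp[lp$side == "outside", , drop = FALSE]
  len <- lp$end - lp$start + 1
  lp <- lp[len >= L_min & len <= L_max, , drop = FALSE]
  data.frame(start = lp$start, end = lp$end,
             peptide = substring(seq, lp$start, lp$end),
             stringsAsFactors = FALSE)
}
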