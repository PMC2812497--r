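# Functional genome distribution: all-vs-all ORFeome similarity condensed
# into genome-genome functional distances, a UPGMA dendrogram, and mining of
# conserved / cluster-specific gene sets.

#' Coverage score of one ORF against a target genome
#'
#' Self-normalized similarity: the best-hit bit score against the target
#' divided by the ORF's self-alignment bit score, capped at 1; 0 when there
#' is no qualifying hit.
#'
#' @param best_bits Best-hit bit score against the target genome, or `NA`.
#' @param self_bits Self-alignment bit score (must be > 0).
#' @return A score in \[0, 1\].
#' @export
coverage_score <- function(best_bits, self_bits) {
  if (any(self_bits <= 0)) stop("degenerate ORF: self bit score <= 0")
  s <- ifelse(is.na(best_bits), 0, pmin(1, best_bits / self_bits))
  pmax(0, s)
}

#' Functional genome distance matrix
#'
#' For each ordered genome pair (A, B), `S(A,B)` is the mean coverage score of
#' A's ORFs against B (ORFs shorter than `min_len` residues are excluded as
#' noise). The symmetric functional distance is
#' `D(A,B) = 1 - (S(A,B) + S(B,A)) / 2`, giving a zero-diagonal symmetric
#' matrix with entries in \[0, 1\].
#'
#' @param genomes Named list of [orf_set()] objects (>= 2).
#' @param params [align_params()] used when hits must be computed.
#' @param hits Optional precomputed list of reduced [hit_table()]s covering
#'   every ordered genome pair (queries vs targets); when absent,
#'   [best_hits()] is run.
#' @param prefilter,min_shared_kmers Passed to [best_hits()]; enable the
#'   prefilter for panel-scale runs.
#' @param min_len Minimum ORF length (residues) to enter the means.
#' @return A symmetric numeric matrix with genome labels as dimnames.
#' @export
fgd_distance_matrix <- function(genomes, params = align_params(), hits = NULL,
                                prefilter = FALSE, min_shared_kmers = 4,
                                min_len = 30) {
  if (is.null(names(genomes))) {
    names(genomes) <- vapply(genomes, genome_id, character(1))
  }
  n <- length(genomes)
  if (n < 2) stop("need at least 2 genomes")
  if (any(vapply(genomes, nrow, 1L) == 0)) stop("genome with zero ORFs")
  labs <- names(genomes)
  if (is.null(hits)) hits <- list()
  S <- matrix(1, n, n, dimnames = list(labs, labs))
  selfbits <- lapply(genomes, self_bit_scores, params = params)
  for (i in seq_len(n)) {
    qs <- genomes[[i]]
    keep <- nchar(qs$protein) >= min_len
    if (!any(keep)) stop("genome ", labs[i], " has no ORFs >= ", min_len,
                         " residues")
    for (j in seq_len(n)) {
      if (i == j) next
      key <- paste(labs[i], labs[j], sep = "|")
      ht <- hits[[key]]
      if (is.null(ht)) {
        ht <- best_hits(qs, genomes[[j]], params,
                        prefilter = prefilter,
                        min_shared_kmers = min_shared_kmers)
      }
      ht <- ht[ht$database == labs[j], , drop = FALSE]
      best <- setNames(ht$bitscore, ht$query)
      sc <- coverage_score(best[qs$orf_id[keep]],
                           selfbits[[i]][qs$orf_id[keep]])
      S[i, j] <- mean(sc)
    }
  }
  D <- 1 - (S + t(S)) / 2
  diag(D) <- 0
  validate_distance_matrix(D)
  D
}

#' Validate a functional distance matrix
#'
#' Checks zero diagonal, symmetry (to 1e-9) and entries in \[0, 1\].
#' @param D Numeric square matrix with labels as dimnames.
#' @return `D`, invisibly; errors if invalid.
#' @export
validate_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal not zero")
  if (any(D < -1e-12 | D > 1 + 1e-12)) stop("distances outside [0, 1]")
  invisible(D)
}

#' UPGMA dendrogram from a distance matrix
#'
#' Standard unweighted pair-group agglomeration: repeatedly merge the closest
#' pair of clusters; the distance from a merged cluster to any other is the
#' size-weighted average of its members' distances; the merge node sits at
#' height d/2, yielding an ultrametric rooted tree. Among tied minimal
#' distances the pair whose sorted label pair (labelled by each cluster's
#' lexicographically smallest leaf) is smallest is merged, making the result
#' deterministic.
#'
#' @param D Symmetric distance matrix with unique labels as dimnames.
#' @return An [ape::read.tree()] `phylo` object (rooted, ultrametric).
#' @export
upgma <- function(D) {
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix not symmetric")
  labs <- rownames(D)
  n <- length(labs)
  if (n < 2) stop("need >= 2 genomes")
  merges <- upgma_merge_sequence(D)
  newick <- setNames(labs, labs)
  height <- setNames(rep(0, n), labs)
  for (m in merges) {
    h <- m$dist / 2
    a <- m$pair[1]; b <- m$pair[2]
    newick[[a]] <- sprintf("(%s:%.10g,%s:%.10g)", newick[[a]], h - height[[a]],
                           newick[[b]], h - height[[b]])
    height[[a]] <- h
    newick <- newick[names(newick) != b]
    height <- height[names(height) != b]
  }
  ape::read.tree(text = paste0(newick[[1]], ";"))
}

#' UPGMA merge sequence
#'
#' The ordered list of merges [upgma()] performs; exposed so the clustering
#' path itself can be audited and compared against independent
#' implementations.
#'
#' @param D Symmetric distance matrix with labels.
#' @return List of merges, each a list with `pair` (the two cluster labels,
#'   each cluster labelled by its lexicographically smallest leaf, sorted) and
#'   `dist` (the merge distance).
#' @export
upgma_merge_sequence <- function(D) {
  labs <- rownames(D)
  active <- setNames(as.list(labs), labs)  # label -> member leaves
  d <- D
  merges <- list()
  while (length(active) > 1) {
    cur <- names(active)
    nn <- length(cur)
    best <- NULL
    for (i in seq_len(nn - 1)) {
      for (j in (i + 1):nn) {
        pair <- sort(c(cur[i], cur[j]))
        dij <- d[cur[i], cur[j]]
        if (is.null(best) || dij < best$dist - 1e-15 ||
            (abs(dij - best$dist) <= 1e-15 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(pair = pair, dist = dij)
        }
      }
    }
    a <- best$pair[1]; b <- best$pair[2]
    na <- length(active[[a]]); nb <- length(active[[b]])
    others <- setdiff(cur, c(a, b))
    for (k in others) {
      d[a, k] <- d[k, a] <- (na * d[a, k] + nb * d[b, k]) / (na + nb)
    }
    active[[a]] <- c(active[[a]], active[[b]])
    active[[b]] <- NULL
    d <- d[names(active), names(active), drop = FALSE]
    merges[[length(merges) + 1]] <- best
  }
  merges
}

#' Mine conserved-core and cluster-specific gene sets
#'
#' Gene sets of a reference genome relative to a genome cluster, based on
#' best-hit e-values: `conserved_core` holds ORFs hit in every cluster genome
#' at e-value <= `cutoff` that are also found outside the cluster (some
#' outside hit <= `e_floor`); `cluster_specific` holds ORFs hit in every
#' cluster genome at <= `cutoff` with no outside hit <= `e_floor`. With an
#' empty outside panel the outside conditions are vacuous and the two sets
#' coincide.
#'
#' @param reference The reference [orf_set()]; must belong to `cluster`.
#' @param hits List of reduced [hit_table()]s of reference queries vs each
#'   panel genome, or one combined `HitTable` (`database` = genome label).
#' @param cluster Character vector of cluster genome labels (including the
#'   reference).
#' @param outside Character vector of outside-panel genome labels.
#' @param cutoff Conservation e-value cutoff (default 1e-100).
#' @param e_floor Presence/absence e-value floor (default 1e-3).
#' @return A list of class `GeneSets` with `conserved_core` and
#'   `cluster_specific` character vectors.
#' @export
mine_gene_sets <- function(reference, hits, cluster, outside = character(),
                           cutoff = 1e-100, e_floor = 1e-3) {
  if (cutoff > e_floor) stop("cutoff must be <= e_floor")
  if (length(cluster) == 0) stop("cluster must be non-empty")
  if (!genome_id(reference) %in% cluster) {
    stop("reference genome not in cluster")
  }
  if (is.data.frame(hits)) hits <- list(hits)
  ht <- do.call(rbind, lapply(hits, as.data.frame))
  evmat <- function(genomes) {
    sapply(genomes, function(g) {
      rows <- ht[ht$database == g, , drop = FALSE]
      setNames(rows$evalue, rows$query)[reference$orf_id]
    })
  }
  ids <- reference$orf_id
  ev_cluster <- matrix(evmat(cluster), nrow = length(ids))
  in_all <- rowSums(!is.na(ev_cluster) & ev_cluster <= cutoff) ==
    length(cluster)
  if (length(outside) > 0) {
    ev_out <- matrix(evmat(outside), nrow = length(ids))
    present_out <- rowSums(!is.na(ev_out) & ev_out <= e_floor, na.rm = TRUE) > 0
  } else {
    present_out <- rep(TRUE, length(ids))  # vacuous
  }
  core <- ids[in_all & present_out]
  specific <- ids[in_all & (length(outside) == 0 | !present_out)]
  structure(list(conserved_core = core, cluster_specific = specific,
                 cluster = cluster, outside = outside,
                 cutoff = cutoff, e_floor = e_floor),
            class = "GeneSets")
}
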