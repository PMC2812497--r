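# Independent oracles and fixture builders used across the test suite.

# Naive full-matrix Smith-Waterman with affine gaps (three-state DP).
# A gap of length L costs gap_open + L * gap_extend.
naive_sw <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A); n <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)
  Iy <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      diag_best <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1], 0)
      M[i, j] <- diag_best + mat[A[i - 1], B[j - 1]]
      Ix[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                      Ix[i - 1, j] - gap_extend)
      Iy[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                      Iy[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# Brute-force UPGMA that rescans the full leaf-level matrix at every step:
# cluster-cluster distance recomputed as the plain mean over all member leaf
# pairs (equivalent to, but independently derived from, the weighted update).
brute_upgma_merges <- function(D) {
  labs <- rownames(D)
  clusters <- setNames(lapply(labs, identity), labs)
  merges <- list()
  while (length(clusters) > 1) {
    cur <- names(clusters)
    best <- NULL
    for (i in seq_len(length(cur) - 1)) {
      for (j in (i + 1):length(cur)) {
        mem_i <- clusters[[cur[i]]]
        mem_j <- clusters[[cur[j]]]
        dij <- mean(D[mem_i, mem_j, drop = FALSE])
        pair <- sort(c(cur[i], cur[j]))
        better <- is.null(best) || dij < best$dist - 1e-15 ||
          (abs(dij - best$dist) <= 1e-15 &&
           paste(pair, collapse = "\r") <
             paste(best$pair, collapse = "\r"))
        if (better) best <- list(pair = pair, dist = dij)
      }
    }
    a <- best$pair[1]; b <- best$pair[2]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
    merges[[length(merges) + 1]] <- best
  }
  merges
}

random_protein_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}

random_dna_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# symmetric random distance matrix in [0, 1] with zero diagonal
random_distance_matrix <- function(n) {
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# reciprocal-overlap fraction of two integer intervals
reciprocal_overlap <- function(a, b) {
  ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  min(ov / (a[2] - a[1] + 1), ov / (b[2] - b[1] + 1))
}

# Robinson-Foulds distance between two trees (unrooted comparison)
rf_distance <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                            method = "PH85"))
}

blosum62_test_matrix <- function() {
  p <- align_params()
  p$matrix
}

# random ultrametric tree whose internal-node heights are drawn from a
# well-separated grid, so distinct divergence levels stay distinguishable
random_separated_tree <- function(n = 6, min_h = 0.05, max_h = 0.35) {
  hs <- sort(sample(seq(min_h, max_h, length.out = 11), n - 1))
  cl <- setNames(as.list(paste0("t", 1:n)), paste0("t", 1:n))
  ht <- setNames(rep(0, n), names(cl))
  for (h in hs) {
    pick <- sample(names(cl), 2)
    a <- pick[1]; b <- pick[2]
    cl[[a]] <- sprintf("(%s:%.6f,%s:%.6f)", cl[[a]], h - ht[[a]],
                       cl[[b]], h - ht[[b]])
    ht[[a]] <- h
    cl[[b]] <- NULL
    ht <- ht[names(ht) != b]
  }
  ape::read.tree(text = paste0(cl[[1]], ";"))
}
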