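# Functional distance matrix, UPGMA, and gene-set mining.

test_that("coverage score is the capped bit-score ratio", {
  expect_equal(coverage_score(50, 50), 1)
  expect_equal(coverage_score(80, 50), 1)       # capped
  expect_equal(coverage_score(NA, 50), 0)       # no hit
  expect_equal(coverage_score(20, 50), 0.4)
  expect_error(coverage_score(10, 0), "degenerate")
})

test_that("distance matrix matches a hand-computed toy panel", {
  # three genomes x 4 ORFs; identical protein "MKTW" everywhere so that all
  # self bit scores are equal, with hit bit scores planted as fixed fractions
  # of that self score
  p <- align_params()
  mk_set <- function(g) orf_set(g, paste0(tolower(g), 1:4),
                                rep(strrep("MKTW", 10), 4))
  gs <- list(A = mk_set("A"), B = mk_set("B"), C = mk_set("C"))
  sb <- unname(self_bit_scores(gs$A, p)[1])
  plant <- function(qg, sg, ratios) {
    qs <- gs[[qg]]$orf_id
    keep <- !is.na(ratios)
    hit_table(query = qs[keep], query_genome = qg,
              subject = paste0(tolower(sg), seq_along(qs))[keep],
              database = sg,
              evalue = rep(1e-50, sum(keep)), bitscore = sb * ratios[keep])
  }
  # planted coverage ratios per ORF (NA = no hit)
  hits <- list(
    "A|B" = plant("A", "B", c(1, .8, .6, NA)),   # S(A,B) = 0.6
    "B|A" = plant("B", "A", c(1, 1, .4, NA)),    # S(B,A) = 0.6
    "A|C" = plant("A", "C", c(.4, NA, NA, NA)),  # S(A,C) = 0.1
    "C|A" = plant("C", "A", c(.2, .2, NA, NA)),  # S(C,A) = 0.1
    "B|C" = plant("B", "C", c(NA, NA, NA, NA)),  # S(B,C) = 0
    "C|B" = plant("C", "B", c(.8, NA, NA, NA)))  # S(C,B) = 0.2
  D <- fgd_distance_matrix(gs, p, hits = hits)
  # hand symmetrization: D = 1 - (S_ab + S_ba)/2
  expect_equal(D["A", "B"], 1 - (0.6 + 0.6) / 2)
  expect_equal(D["A", "C"], 1 - (0.1 + 0.1) / 2)
  expect_equal(D["B", "C"], 1 - (0 + 0.2) / 2)
  expect_equal(diag(D), c(A = 0, B = 0, C = 0))
  expect_equal(D, t(D))
})

test_that("genomes sharing no hits are at distance 1, self-distance 0", {
  set.seed(21)
  a <- orf_set("A", paste0("a", 1:3),
               vapply(rep(60, 3), random_protein_seq, character(1)))
  b <- orf_set("B", paste0("b", 1:3),
               vapply(rep(60, 3), random_protein_seq, character(1)))
  empty <- hit_table()
  D <- fgd_distance_matrix(list(A = a, B = b), hits = list("A|B" = empty,
                                                           "B|A" = empty))
  expect_equal(D["A", "B"], 1)
  expect_equal(diag(D), c(A = 0, B = 0))
})

test_that("UPGMA reproduces the hand-worked three-leaf tree", {
  D <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  # expected ((A:0.1,B:0.1):0.2,C:0.3)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(unname(depths[1:3]), rep(0.3, 3))  # ultrametric at height 0.3
  cherry <- ape::extract.clade(tr, ape::getMRCA(tr, c("A", "B")))
  expect_equal(sort(cherry$tip.label), c("A", "B"))
  expect_equal(sort(unique(round(tr$edge.length, 9))), c(0.1, 0.2, 0.3))
})

test_that("UPGMA merge sequence equals the brute-force rescanning oracle", {
  set.seed(22)
  for (rep in 1:20) {
    D <- random_distance_matrix(8)
    got <- upgma_merge_sequence(D)
    want <- brute_upgma_merges(D)
    expect_equal(length(got), length(want))
    for (k in seq_along(got)) {
      expect_equal(got[[k]]$pair, want[[k]]$pair)
      expect_equal(got[[k]]$dist, want[[k]]$dist)
    }
  }
})

test_that("UPGMA agrees with average-linkage hclust on tie-free matrices", {
  set.seed(23)
  for (rep in 1:5) {
    D <- random_distance_matrix(7)
    tr <- upgma(D)
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    # merge heights match hclust heights / 2
    my_heights <- sort(vapply(upgma_merge_sequence(D), `[[`, 1, "dist")) / 2
    expect_equal(my_heights, sort(hc$height) / 2, tolerance = 1e-9)
    # and the induced topologies agree
    expect_equal(rf_distance(tr, ape::as.phylo(hc)), 0)
  }
})

test_that("UPGMA trees are ultrametric and reject asymmetric input", {
  set.seed(24)
  D <- random_distance_matrix(6)
  tr <- upgma(D)
  depths <- ape::node.depth.edgelength(tr)
  expect_lt(diff(range(depths[seq_len(6)])), 1e-9)
  D2 <- D
  D2[1, 2] <- D2[1, 2] + 1e-3
  expect_error(upgma(D2), "symmetric")
})

test_that("gene-set mining honours cutoffs, presence and the degenerate cluster", {
  ref <- orf_set("A", c("g1", "g2", "g3"), rep(strrep("MKTW", 20), 3))
  mk_hits <- function(db, ev) {
    keep <- !is.na(ev)
    hit_table(query = ref$orf_id[keep], query_genome = "A",
              subject = paste0("s", which(keep)), database = db,
              evalue = ev[keep], bitscore = 100)
  }
  hits <- list(
    mk_hits("A", c(0, 0, 0)),                      # self
    mk_hits("B", c(1e-120, 1e-120, 1e-50)),
    mk_hits("C", c(1e-130, 1e-110, 1e-120)),
    mk_hits("X", c(1e-50, NA, 1e-4)))              # outside genome
  gs <- mine_gene_sets(ref, hits, cluster = c("A", "B", "C"),
                       outside = "X", cutoff = 1e-100, e_floor = 1e-3)
  # g1: conserved in cluster, present outside -> core, not specific
  # g2: conserved in cluster, absent outside  -> specific, not core
  # g3: 1e-50 in B fails the 1e-100 cutoff    -> neither
  expect_equal(gs$conserved_core, "g1")
  expect_equal(gs$cluster_specific, "g2")
  expect_length(intersect(gs$conserved_core, gs$cluster_specific), 0)

  # degenerate cluster: reference only, no outside panel
  gs2 <- mine_gene_sets(ref, hits, cluster = "A", cutoff = 1e-100,
                        e_floor = 1e-3)
  expect_equal(gs2$conserved_core, c("g1", "g2", "g3"))  # self-hits e = 0
  expect_equal(gs2$cluster_specific, gs2$conserved_core)

  expect_error(mine_gene_sets(ref, hits, cluster = "B"), "reference")
  expect_error(mine_gene_sets(ref, hits, cluster = "A", cutoff = 1e-2,
                              e_floor = 1e-3), "cutoff")
})

test_that("planted clade-specific and core families are recovered exactly on a synthetic panel", {
  sim <- small_sim()
  p <- align_params()
  ref <- sim$orfsets$A
  labs <- names(sim$orfsets)
  hits <- lapply(setdiff(labs, "A"), function(g) {
    best_hits(ref, sim$orfsets[[g]], p, prefilter = TRUE)
  })
  self_ht <- hit_table(query = ref$orf_id, query_genome = "A",
                       subject = ref$orf_id, database = "A",
                       evalue = 0, bitscore = self_bit_scores(ref, p))
  gs <- mine_gene_sets(ref, c(hits, list(self_ht)),
                       cluster = c("A", "B", "C"),
                       outside = c("D", "E", "F"),
                       cutoff = 1e-20, e_floor = 1e-3)
  truth <- sim$truth
  present <- function(fam, genomes) {
    all(vapply(genomes, function(g) {
      any(truth$genome == g & truth$family == fam)
    }, logical(1)))
  }
  ref_truth <- truth[truth$genome == "A", ]
  fams <- ref_truth$family
  want_core <- ref_truth$orf_id[vapply(fams, function(f)
    present(f, c("A", "B", "C")) &&
      (present(f, "D") || present(f, "E") || present(f, "F")),
    logical(1))]
  want_specific <- ref_truth$orf_id[vapply(fams, function(f)
    present(f, c("A", "B", "C")) &&
      !present(f, "D") && !present(f, "E") && !present(f, "F"),
    logical(1))]
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  # at this reduced scale (120-codon genes) a rare chance alignment can move
  # a single gene across the presence/absence boundary; recovery must still
  # be near-exact
  expect_gte(jaccard(gs$conserved_core, want_core), 0.9)
  expect_gte(jaccard(gs$cluster_specific, want_specific), 0.8)
  expect_gt(length(intersect(gs$cluster_specific,
                             ref_truth$orf_id[ref_truth$clade_specific])),
            0.8 * sum(ref_truth$clade_specific))
})

test_that("functional distance increases with simulated divergence", {
  # 20 seeded replicates on random ultrametric trees with well-separated
  # merge heights. Leaf pairs sharing an ancestor have identical path
  # lengths, so the monotonicity of D in divergence is assessed on the
  # distinct divergence levels (mean D per level vs the level itself).
  rhos <- vapply(1:20, function(s) {
    set.seed(100 + s)
    tr <- random_separated_tree(6, min_h = 0.05, max_h = 0.35)
    sim <- simulate_clade(sim_config(tree = tr, clade = tr$tip.label[1:2],
                                     n_core = 20, n_clade_specific = 0,
                                     n_hgt = 0, gene_len_mean = 100,
                                     gene_len_sd = 10, loss_prob = 0,
                                     membrane_fraction = 0, sp_fraction = 0,
                                     seed = 200 + s))
    D <- fgd_distance_matrix(sim$orfsets, hits = NULL, prefilter = TRUE)
    P <- ape::cophenetic.phylo(sim$tree)[rownames(D), colnames(D)]
    ut <- upper.tri(D)
    level <- round(P[ut], 9)
    mean_d <- tapply(D[ut], level, mean)
    cor(as.numeric(names(mean_d)), mean_d, method = "spearman")
  }, numeric(1))
  expect_true(all(rhos > 0.9))
})
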