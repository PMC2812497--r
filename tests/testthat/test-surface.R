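# Transmembrane-helix prediction, signal peptides, the candidate cascade and
# loop extraction.

test_that("a hydrophobic Leu run between Ser flanks yields exactly one helix", {
  seq <- paste0(strrep("S", 20), strrep("L", 21), strrep("S", 20))
  topo <- predict_tmh(seq)
  expect_equal(topo$tmh_count, 1L)
  # hand-worked hydropathy: windows with >= 10 Leu (centres 21..41) pass the
  # 1.6 threshold, so the helix covers the Leu run within +/- 2 residues
  expect_lte(abs(topo$tmh_intervals[1, "start"] - 21), 2)
  expect_lte(abs(topo$tmh_intervals[1, "end"] - 41), 2)
})

test_that("acidic sequences and short sequences have no helices", {
  expect_equal(predict_tmh(strrep("DE", 30))$tmh_count, 0L)
  expect_equal(predict_tmh("MKTW")$tmh_count, 0L)  # shorter than the window
  expect_error(predict_tmh("MK9T"), "invalid")
})

test_that("orientation follows the positive-inside rule", {
  helix <- strrep("L", 21)
  n_in <- paste0("M", strrep("KR", 4), strrep("S", 11), helix, strrep("S", 20))
  expect_equal(predict_tmh(n_in)$orientation, "N_in")
  c_in <- paste0(strrep("S", 20), helix, strrep("S", 11), strrep("KR", 4), "M")
  expect_equal(predict_tmh(c_in)$orientation, "N_out")
  # no charges anywhere: tie resolves to N_in
  tie <- paste0(strrep("S", 20), helix, strrep("S", 20))
  expect_equal(predict_tmh(tie)$orientation, "N_in")
})

test_that("loops alternate sides consistently with orientation", {
  seq <- paste0(strrep("S", 20), strrep("L", 21), strrep("S", 20),
                strrep("L", 21), strrep("S", 20))
  topo <- predict_tmh(seq)
  expect_equal(topo$tmh_count, 2L)
  sides <- topo$loops$side
  expect_equal(length(sides), 3L)
  expect_true(all(sides == c("inside", "outside", "inside") |
                    sides == c("outside", "inside", "outside")))
})

test_that("helix intervals stay within the 15-35 residue band", {
  set.seed(41)
  for (i in 1:50) {
    planted <- plant_surface_features(
      orf_set("g", "x", random_protein_seq(sample(150:400, 1))),
      membrane_fraction = 1, sp_fraction = 0)
    topo <- predict_tmh(planted$orfs$protein[1])
    if (topo$tmh_count > 0) {
      len <- topo$tmh_intervals[, "end"] - topo$tmh_intervals[, "start"] + 1
      expect_true(all(len >= 15 & len <= 35))
      expect_true(all(diff(as.vector(t(topo$tmh_intervals))) > 0))
    }
  }
})

test_that("signal-peptide heuristic follows the n/h/c template", {
  pos <- paste0("MKK", strrep("L", 10), "ALA", strrep("S", 30))
  got <- predict_signal_peptide(pos)
  expect_true(got$sp_flag)
  expect_equal(got$cleavage, 17L)  # residue after the A-L-A motif
  # no charged n-region / no hydrophobic h-region -> negative
  expect_false(predict_signal_peptide(
    paste0(strrep("S", 40), "ALA", strrep("S", 10)))$sp_flag)
  # too short -> negative
  expect_false(predict_signal_peptide("MKKLLLLLLLLLLALA")$sp_flag)
})

test_that("stringency presets combine by OR", {
  # h-region of Ala (KD 1.8): mean 1.8 passes default/loose but, once
  # averaged with its Met neighbour, fails strict
  borderline <- paste0("MKK", strrep("A", 11), "A", "SA", strrep("T", 30))
  # construct: h-window mean between 1.2 and 1.5 -> loose only
  weak <- paste0("MKK", strrep("AS", 7), "ALA", strrep("T", 30))
  single <- vapply(c("strict", "default", "loose"), function(st) {
    predict_signal_peptide(weak, st)$sp_flag
  }, logical(1))
  combined <- predict_signal_peptide(weak,
                                     c("strict", "default", "loose"))$sp_flag
  expect_equal(combined, any(single))
  if (any(single) && !all(single)) {
    expect_true(combined)  # positive under OR despite a failing preset
  }
})

test_that("the cascade reproduces the hand-traced eight-ORF fixture", {
  ft <- feature_table(
    orf_id = paste0("o", 1:8),
    tmh_count = c(0L, 0L, 2L, 1L, 3L, 2L, 4L, 6L),
    sp_flag = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    top_hit_group = c("ingroup", "ingroup", "ingroup", "ingroup", "other",
                      "ingroup", "ingroup", "ingroup"),
    is_transposase = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                       FALSE),
    is_adhesin = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    conservation_count = c(5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L))
  rep <- cascade_filter(ft, min_conservation = 3, panel_size = 5)
  # hand trace: o1, o2 soluble -> dropped at pooling (8 -> 6); o3 transposase,
  # o4 adhesin, o5 non-in-group hit -> dropped (6 -> 3); all survivors
  # conserved (3 -> 3); groups by the 4-helix cut: {o6, o7} / {o8}
  expect_equal(unname(rep$step_counts),
               c(8L, 6L, 3L, 3L))
  expect_setequal(rep$group_A, c("o6", "o7"))
  expect_equal(rep$group_B, "o8")
  expect_equal(sum(is.na(rep$audit$removed_at)), 3L)
  expect_equal(rep$audit$reason[rep$audit$orf_id == "o3"], "transposase")
})

test_that("group sizes always partition the refined count", {
  set.seed(42)
  for (i in 1:1000) {
    n <- sample(3:25, 1)
    ft <- feature_table(
      orf_id = paste0("o", seq_len(n)),
      tmh_count = sample(0:8, n, TRUE),
      sp_flag = runif(n) < 0.4,
      top_hit_group = sample(c("ingroup", "other", "none"), n, TRUE,
                             prob = c(.6, .2, .2)),
      is_transposase = runif(n) < 0.1,
      is_adhesin = runif(n) < 0.1,
      conservation_count = sample(0:5, n, TRUE))
    rep <- cascade_filter(ft, min_conservation = sample(0:4, 1),
                          panel_size = 5)
    expect_equal(length(rep$group_A) + length(rep$group_B),
                 unname(rep$step_counts["conservation"]))
    expect_true(all(diff(rep$step_counts) <= 0))
    expect_length(intersect(rep$group_A, rep$group_B), 0)
    removed <- rep$audit[!is.na(rep$audit$removed_at), ]
    expect_true(all(nzchar(removed$reason)))
  }
})

test_that("cascade rejects inconsistent inputs", {
  expect_error(feature_table("o1", -1L, FALSE), "negative")
  ft <- feature_table("o1", 2L, FALSE, conservation_count = 9L)
  expect_error(cascade_filter(ft, 1, 5), "panel_size")
  expect_error(cascade_filter(feature_table("o1", 2L, FALSE), 6, 5),
               "min_conservation")
})

test_that("surface loops come only from the outside face, within length bounds", {
  seq <- paste0(strrep("S", 20), strrep("L", 21), strrep("S", 20),
                strrep("L", 21), strrep("S", 60))
  topo <- predict_tmh(seq)
  expect_equal(topo$tmh_count, 2L)
  loops <- extract_surface_loops(seq, topo, L_min = 8, L_max = 40)
  outside <- topo$loops[topo$loops$side == "outside", ]
  expect_equal(nrow(loops), sum(outside$end - outside$start + 1 >= 8 &
                                  outside$end - outside$start + 1 <= 40))
  if (nrow(loops) > 0) {
    expect_true(all(nchar(loops$peptide) >= 8 & nchar(loops$peptide) <= 40))
    expect_equal(loops$peptide,
                 substring(seq, loops$start, loops$end))
  }
  # flipping the orientation by moving the charges flips the returned loops
  flipped <- paste0(strrep("S", 20), strrep("L", 21), strrep("S", 9),
                    strrep("K", 11), strrep("L", 21), strrep("S", 60))
  topo2 <- predict_tmh(flipped)
  if (topo2$tmh_count == 2) {
    expect_false(identical(topo$loops$side, topo2$loops$side))
  }
})

test_that("predictors are deterministic", {
  set.seed(43)
  s <- random_protein_seq(250)
  expect_identical(predict_tmh(s), predict_tmh(s))
  expect_identical(predict_signal_peptide(s, c("strict", "loose")),
                   predict_signal_peptide(s, c("strict", "loose")))
})

test_that("planted helices are recovered with high sensitivity and few false calls", {
  set.seed(44)
  n <- 200
  lens <- sample(150:450, n, replace = TRUE)
  base <- orf_set("g", paste0("p", seq_len(n)),
                  vapply(lens, random_protein_seq, character(1)))
  planted <- plant_surface_features(base, membrane_fraction = 0.5,
                                    sp_fraction = 0)
  truth <- planted$truth
  hits <- 0; total <- 0; false_pos <- 0; n_soluble <- 0
  for (i in seq_len(n)) {
    topo <- predict_tmh(planted$orfs$protein[i])
    iv_true <- decode_intervals(truth$helix_intervals[i])
    if (truth$membrane[i]) {
      total <- total + nrow(iv_true)
      for (k in seq_len(nrow(iv_true))) {
        ov <- apply(topo$tmh_intervals, 1, reciprocal_overlap,
                    b = iv_true[k, ])
        if (length(ov) > 0 && max(ov) >= 0.5) hits <- hits + 1
      }
    } else {
      n_soluble <- n_soluble + 1
      if (topo$tmh_count > 0) false_pos <- false_pos + 1
    }
  }
  expect_gte(hits / total, 0.9)
  expect_lte(false_pos / n_soluble, 0.1)
})

test_that("planted signal peptides are positive under the combined rule", {
  set.seed(45)
  base <- orf_set("g", paste0("p", 1:40),
                  vapply(sample(120:300, 40, TRUE), random_protein_seq,
                         character(1)))
  planted <- plant_surface_features(base, membrane_fraction = 0,
                                    sp_fraction = 1)
  for (i in which(planted$truth$sp)) {
    got <- predict_signal_peptide(planted$orfs$protein[i],
                                  c("strict", "default", "loose"))
    expect_true(got$sp_flag)
    expect_equal(got$cleavage, planted$truth$sp_cleavage[i])
  }
})

test_that("imported predictor tables are parsed with their column maps", {
  f <- withr::local_tempfile()
  writeLines(c(
    "orf1  len=312  ExpAA=110.2  First60=2.1  PredHel=2  Topology=i12-31o46-65i",
    "orf2  len=100  ExpAA=0.0    First60=0.0  PredHel=0  Topology=i"), f)
  tm <- read_tmhmm(f)
  expect_equal(tm$tmh_count, c(2L, 0L))
  expect_equal(tm$tmh_intervals[[1]][2, ], c(46L, 65L))

  g <- withr::local_tempfile()
  writeLines(c("# signal peptide summary",
               "orf1\tgram+\tY\t24", "orf1\tgram-\tN\t-", "orf1\teuk\tN\t-",
               "orf2\tgram+\tN\t-", "orf2\tgram-\tN\t-"), g)
  sp <- read_signalp(g)
  expect_equal(sp$sp_flag, c(TRUE, FALSE))
  expect_equal(sp$models_positive, c(1L, 0L))
})
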