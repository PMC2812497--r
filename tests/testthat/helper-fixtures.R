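# Shared fixtures. Heavy simulations are memoised so several test files can
# reuse them without recomputation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Default-scale study conditions (6 leaves, 200 core families, 50
# clade-specific, seed 1) with the all-vs-all reference hits needed by the
# distance and differential analyses.
default_sim <- function() {
  memo("default_sim", simulate_clade(sim_config(seed = 1)))
}

default_fgd <- function() {
  memo("default_fgd", {
    sim <- default_sim()
    fgd_distance_matrix(sim$orfsets, align_params(), prefilter = TRUE)
  })
}

# reference-vs-all best hits at default scale (reference genome "A")
default_ref_hits <- function() {
  memo("default_ref_hits", {
    sim <- default_sim()
    p <- align_params()
    labs <- names(sim$orfsets)
    hits <- lapply(setdiff(labs, "A"), function(g) {
      best_hits(sim$orfsets[["A"]], sim$orfsets[[g]], p, prefilter = TRUE)
    })
    names(hits) <- setdiff(labs, "A")
    hits
  })
}

# small clade for fast recovery tests
small_sim <- function() {
  memo("small_sim", simulate_clade(
    sim_config(n_core = 30, n_clade_specific = 10, n_hgt = 4,
               gene_len_mean = 120, gene_len_sd = 20, seed = 7)))
}

# GenBank-lite toy record: three CDS (t1-t3), t3 lacking /translation.
# Genome: ATGAAAACC TTA TCCTCCCAT TTA ATGTGCTGA TTT
#   t1 1..9   (+) ATGAAAACC          -> MKT
#   t2 complement(13..21)            -> revcomp(TCCTCCCAT) = ATGGGAGGA -> MGG
#   t3 25..33 (+) ATGTGCTGA          -> MC (trailing stop dropped)
write_genbank_fixture <- function(path, truncated = FALSE) {
  seq <- "ATGAAAACCTTATCCTCCCATTTAATGTGCTGATTT"
  lines <- c(
    "LOCUS       toyrep          36 bp    DNA     circular BCT 01-JAN-2010",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..9",
    "                     /locus_tag=\"t1\"",
    "                     /product=\"toy protein one\"",
    "                     /translation=\"MKT\"",
    "     CDS             complement(13..21)",
    "                     /locus_tag=\"t2\"",
    "                     /product=\"toy protein two\"",
    "                     /translation=\"MGG\"",
    "     CDS             25..33",
    "                     /locus_tag=\"t3\"",
    "                     /product=\"toy protein three\"",
    "ORIGIN",
    paste0("        1 ", tolower(seq)),
    if (!truncated) "//")
  writeLines(lines, path)
  path
}
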