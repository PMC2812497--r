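---
title: "Methods: comparative ORFeome mining with orfminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative ORFeome mining with orfminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`orfminer` nominates gene targets in lineage-restricted microbes — the
motivating case is rumen methanogens, where methane-mitigation strategies
need genes that are universal and essential within the methanogen lineage
yet absent from the surrounding microbiota and the host. This vignette
documents the models behind each stage, the parameters that matter, the
synthetic data the tests rest on, and the design decisions taken where the
method space was genuinely open.

## Pairwise similarity and its statistics

All homology in the package flows through Smith–Waterman local alignment
with affine gaps (BLOSUM62; gap open 11, extend 1; a gap of length $L$
costs $11 + L$). Raw scores $S$ become bit scores and e-values through the
gapped Karlin–Altschul parameters published for this scoring system
($\lambda = 0.267$, $K = 0.041$):

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'},$$

with $m,n$ the two sequence lengths. Two deliberate simplifications are
documented rather than hidden: no composition-based statistic adjustment,
and no low-complexity masking. The latter matters: designed membrane
proteins contain long runs over a six-letter hydrophobic alphabet, and
unrelated membrane proteins can reach nominally significant pairwise
e-values (~1e-4) through helix-on-helix chance alignments.

Because of that, the layer that emulates a *database* search — the
differential homology analysis — optionally rescales each best hit to the
database-level statistic $E = m N 2^{-S'}$, where $N$ is the pooled residue
count of the database searched. This is the quantity a database search
engine reports, and it is what the trust-level discretization is meant to
consume; the pairwise $mn$ statistic is kept for single alignments, where
it is the correct search space.

An optional seed prefilter skips pairs sharing fewer than 2 distinct
5-mers. Five-mers rather than shorter words: random pairs of ~300-residue
proteins share ~11 3-mers on average, so a 3-mer filter would pass nearly
everything, while homologs at the divergence levels of interest (≤ 0.7
expected substitutions/site, ≥ 50% identity) retain several 5-mers with
high probability. The filter is off by default, so that results are exactly
the exhaustive all-pairs search unless the caller opts in; panel-scale
analyses (the pipeline, the distance matrix) opt in.

## Functional genome distance

For ORF $i$ of genome $A$, the coverage score against genome $B$ is the
best-hit bit score normalized by the ORF's self-alignment bit score, capped
at 1 (0 when no hit qualifies). The self score is computed from the
substitution-matrix diagonal, which is the exact optimal local
self-alignment under BLOSUM62 (every diagonal entry is positive). Genome
similarity $S(A,B)$ is the mean coverage over $A$'s ORFs — ORFs shorter
than 30 residues are excluded as noise — and

$$D(A,B) = 1 - \tfrac{1}{2}\left(S(A,B) + S(B,A)\right).$$

This scoring function was an open design point: it is self-normalized
(identical genomes sit at 0), bounded in $[0,1]$, symmetric by
construction, and monotone in divergence on simulated clades. UPGMA is
implemented in-package because the clustering path itself is part of the
contract: ties between minimal distances are broken by the
lexicographically smallest sorted pair of cluster labels (each cluster
labelled by its smallest leaf), making the merge sequence fully
deterministic and auditable (`upgma_merge_sequence()`); `stats::hclust`
with average linkage serves as an independent cross-check in the tests.

Gene-set mining declares an ORF *conserved-core* when every cluster genome
hits it at or below the conservation cutoff (default 1e-100; 1e-20 in the
reduced-scale tests) **and** it is found outside the cluster at the
presence floor (1e-3), and *cluster-specific* when the cluster condition
holds but no outside hit reaches the floor. Requiring outside presence for
the core set keeps the two sets disjoint whenever an outside panel exists;
with no outside panel both conditions are vacuous and the sets coincide.

## Trust levels and the differential

Best-hit e-values are discretized as
$T = \min(T_\mathrm{cap}, \lfloor -\log_{10} E \rfloor)$, with $T = 0$
above the presence floor (1e-3) and $T = T_\mathrm{cap} = 200$ at $E = 0$.
The differential $\Delta = T_\mathrm{out} - T_\mathrm{in}$ is reported for
every ORF, and the class rules use two thresholds: present at
$T \ge \tau_p = 10$ (i.e. $E \le 10^{-10}$), absent at $T < \tau_a = 3$.
Borderline profiles fall back to *shared*, the conservative call. The
thresholds are surfaced in the configuration; the discretization is
order-preserving and bounded, so any monotone re-binning gives the same
ranking.

## Surface-protein prediction

The built-in predictors are light-weight, transparent stand-ins for the
heavy HMM/NN tools a production annotation would use; the cascade prefers
imported prediction tables and falls back to these.

**Transmembrane helices.** Mean Kyte–Doolittle hydropathy over 19-residue
windows, each value assigned to the window centre. Maximal runs of centres
at or above 1.6 become helices, subject to two constraints with physical
readings: a run must span at least 9 centres (a hydrophobic stretch of
roughly 18 residues, the minimum membrane span — shorter excursions are
treated as noise, the hydropathy-method analogue of a state-duration
constraint), and reported helices are clamped to the canonical 15–35
residue band (short runs widened symmetrically, long runs split evenly).
Orientation follows the positive-inside rule: lysines/arginines within 15
residues of a helix boundary are summed over the two alternating loop
parities and the richer side faces the cytoplasm, ties defaulting to
N-in. Terminal tails count as loops — the method cannot distinguish a tail
from a loop, and excluding tails would silently drop single-helix
proteins' ectodomains.

**Signal peptides.** A tripartite template over the first 45 residues:
≥ 1 K/R in positions 1–5 (n-region), an 8-residue window in positions 4–30
with mean hydropathy above the stringency threshold (strict 1.8 / default
1.5 / loose 1.2; h-region), and an A-x-A motif whose second alanine lies at
positions 16–40, the cleavage site following it (c-region). Multiple
stringencies combine by OR, mirroring the common practice of running a
predictor under several trained models and accepting any positive.

**The cascade.** Four audited steps: pool (any helix or signal peptide);
exclusions (top hit to a non-in-group organism or no homology at all,
transposases, adhesin-like proteins — the last are a separate candidate
class, not discarded science); conservation (hits in at least
`min_conservation` panel genomes — a single configurable threshold standing
in for what is, in practice, manual curation of function and conservation);
and grouping at the 4-helix cut (more helices than that resist heterologous
expression, pushing candidates to the peptide route). Every removal records
exactly one reason, counts are monotone non-increasing, and
$|A| + |B|$ equals the refined count by construction.

## Composition statistics

Windowed GC and GC skew $(G-C)/(G+C)$ tile the replicon (windows wrap on
circular replicons; linear mode keeps full windows only). The cumulative
skew's global minimum is reported as the replication-origin candidate and
the maximum as the terminus — the standard polarity-switch argument; both
extrema are attributes of the profile so an annotation cross-check (e.g. a
replication-initiator gene nearby) remains the caller's decision. Window
and step default to 5000/500 bases, the usual scale for bacterial-sized
replicons; the tests use smaller windows on smaller constructs.

CAI follows the classic definition: per-codon relative adaptiveness
$w = f / f_\mathrm{max-synonym}$ estimated from a reference gene set
(canonically ribosomal proteins; the simulator uses a fixed slice of host
genes), unobserved codons floored at 0.01, and the gene score the geometric
mean of $w$ over codons excluding Met, Trp and stops (single-codon families
carry no information). The HGT flag requires all three evidence lines at
once: $|z_{GC}| \ge 2$ — with $z$ computed against the median and MAD, so
the foreign genes being screened for cannot inflate the scale estimate —
CAI percentile ≤ 0.25, and a non-in-group top hit. At least 20 ORFs are
required to estimate the genome norm at all.

## The synthetic clade and what it does (not) show

The simulator defines the study conditions once: a six-leaf ultrametric
tree `(((A:0.10,B:0.10):0.10,C:0.20):0.15,((D:0.15,E:0.15):0.10,F:0.25):0.10);`
with clade {A, B, C} and reference A; 200 core families; 50 clade-specific
families inserted at the clade ancestor; 10 horizontally acquired genes in
the reference only; gene lengths 300 ± 60 codons (minimum 60); per-branch
gene-loss probability 0.02; 8% membrane and 5% signal-peptide genes; donor
GC offset 0.12. The leaf-to-leaf path lengths (0.2, 0.3, 0.4, 0.5, 0.7
expected substitutions/site) are pairwise distinct by at least 0.1, which
is what topology recovery from a noisy distance needs, and the tree is
clock-like, which is the regime UPGMA assumes. Substitution is uniform
across residues (probability $1-e^{-b}$ per site per branch, uniform
replacement), keeping the identity–path relation closed-form
($\approx e^{-\mathrm{path}}$) at the cost of realism; there are no indels,
so planted feature coordinates survive evolution unchanged. Back-translation
uses a host codon model with one preferred codon per family (weight 4:1)
and a donor model weighting codons by $e^{13 \cdot \mathrm{offset} \cdot
n_{GC}}$, a mapping calibrated so the realized genome-wide GC offset of
donor genes approximates the configured value.

Passing tests on this generator show that each stage recovers the structure
it assumes, at the noise levels the substitution model produces. They do
not show performance on real data: real proteomes have biased residue
composition, indels, domain shuffling, paralogy, and annotation noise, none
of which are emulated; real membrane proteins are not six-letter designs;
and a real out-group database is vastly larger and more redundant than
three simulated genomes. The package's claim is that the machinery is
correct and deterministic, not that the simulator certifies field accuracy.

Ground truth for the differential-classification tests is the *realized*
presence/absence in the emitted data, not the planting intent: per-branch
loss can remove a core family from the entire out-group, and such a gene
genuinely is in-group specific in the data the classifier sees.

## Numerical and engineering choices

* Coordinates are 1-based inclusive internally; BED export converts to
  0-based half-open, with the class in the name column and the differential
  clamped to 0–1000 in the score column.
* Ambiguous residues: B/Z/U map to X with a warning; X scores 0 against
  everything, including itself.
* Best-hit tie-breaking is total: lowest e-value, then highest bit score,
  then lexicographic subject id.
* Test problem sizes: the distance/recovery checks run at the full default
  conditions (200 core families); property tests that need many replicates
  (divergence monotonicity, 20 replicates) run on 20-family, 100-codon
  panels, which preserve the property while keeping each replicate cheap.
* Reduced-scale runs (~120-codon genes) sit close to the noise floor of the
  presence/absence boundary: a single chance alignment can move one gene
  across it, so reduced-scale recovery tests assert near-exact (Jaccard ≥
  0.9) rather than exact recovery. The full-scale checks are exact.
* The divergence-monotonicity property is assessed per distinct divergence
  level (mean distance per level): leaf pairs sharing an ancestor have
  identical path lengths, and tie-corrected rank correlation is bounded
  below 1 by those ties even under perfect monotonicity.
* Everything is seeded; reruns of the pipeline with identical configuration
  and seed are byte-identical, and the run manifest records parameters,
  seed, version and per-stage counts with no timestamps.

## Known limitations

Alignment e-values are approximate (fixed Karlin–Altschul parameters, no
composition adjustment); the TMH/SP predictors are heuristics, not trained
models; localization prediction is carried as an input column, never
computed (no archaeal model worth the name exists); the manual-curation
step of a real target-selection campaign is approximated by one
conservation threshold; and the chemogenomic metabolic list is a curated
input by design — the package intersects it, it does not derive it.
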