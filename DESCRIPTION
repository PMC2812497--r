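Package: orfminer
Title: Comparative ORFeome Mining for Conserved and Lineage-Specific Gene Targets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative genomics toolkit for mining microbial ORFeomes for
    methane-mitigation and antimicrobial gene targets. Implements functional
    genome distribution (FGD) analysis (all-vs-all protein similarity
    condensed into genome-genome functional distances and a UPGMA
    dendrogram), differential homology analysis against an in-group and an
    out-group database via discretized e-value trust levels, a
    reverse-vaccinology cascade for surface-protein candidate selection
    (transmembrane-helix and signal-peptide prediction, conservation
    filtering, extracellular loop extraction), chemogenomic target
    intersection, nucleotide-composition analyses (GC skew, replication
    origin prediction, codon adaptation index, horizontal-gene-transfer
    flagging), and a fully seeded synthetic clade simulator that provides
    ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    Matrix,
    ape,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
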