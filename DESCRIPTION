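Package: casteTE
Title: Transposable-Element Insertions and Caste-Biased Gene Expression in
    Blattodea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline linking transposable-element (TE)
    insertions to caste- and stage-biased gene expression across termites
    and cockroaches. Consolidates redundant multi-tool TE annotations into
    a deduplicated library, computes CpG-aware Kimura 2-parameter
    divergence landscapes, classifies genes as worker/nymph- or
    queen/adult-female-biased from RNA-seq counts, profiles TE-gene
    overlap (exonic/intronic insertions, per-kilobase rates, TE-rich
    flags), performs score-based GO-term enrichment with elim pruning and
    a three-criterion specificity filter, and runs phylogenetic
    comparative statistics (independent contrasts, Poisson log-linear
    contingency models). A synthetic-data module generates every input
    with planted ground truth so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    ape,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
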