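# Shared in-code fixtures.

tiny_config <- function(...) {
  args <- list(seed = 42, n_chroms = 2, chrom_length = 5e5, n_genes = 60,
               te_density = 25, n_libs_per_group = 3, go_terms = 30,
               go_depth = 3)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# hand-built two-gene models object used by the overlap tests:
#   geneA chr1:1001-3000 (+) with exons 1001-1200 and 2601-3000
#   geneB chr1:5001-6000 (-) single exon = whole span
two_gene_models <- function() {
  genes <- data.frame(chrom = "chr1", start = c(1001L, 5001L),
                      end = c(3000L, 6000L), strand = c("+", "-"),
                      gene_id = c("geneA", "geneB"))
  exons <- data.frame(chrom = "chr1",
                      start = c(1001L, 2601L, 5001L),
                      end = c(1200L, 3000L, 6000L),
                      strand = c("+", "+", "-"),
                      gene_id = c("geneA", "geneA", "geneB"),
                      exon_id = c("geneA.e1", "geneA.e2", "geneB.e1"))
  gene_models(genes, exons,
              seqinfo = data.frame(chrom = "chr1", length = 1e5))
}

# DE records with a given number of focal-biased genes at >=2-fold change
# among a given DEG total (remaining DEGs are opposite-biased below the
# fold threshold); used to exercise the reporting arithmetic.
make_bias_records <- function(n_focal, n_deg, focal = "worker_nymph") {
  other <- setdiff(c("worker_nymph", "queen_female"), focal)
  sgn <- function(cl) if (cl == "queen_female") 1 else -1
  lfc <- c(rep(sgn(focal) * 2, n_focal), rep(sgn(other) * 0.5, n_deg - n_focal))
  data.frame(gene_id = sprintf("g%05d", seq_len(n_deg)),
             log2fc = lfc,
             pvalue = 0.001, padj = 0.01)
}
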