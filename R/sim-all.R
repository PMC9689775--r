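#' Run every generator and emit the standard-format files
#'
#' Drives the full synthetic-data module: gene models (GFF3), per-tool TE
#' call sets and mapped copies (BED6+2), copy/consensus alignments (TSV),
#' counts and sample sheet (TSV), GO DAG edges and gene-to-term map
#' (TSV), species tree (newick) and bivariate traits (TSV), plus truth
#' tables for every planted entity. Output is byte-identical for
#' identical configs (single root seed, deterministic per-stage child
#' seeds).
#'
#' The expression truth is generated first so that TE placement can use
#' the per-class insertion multipliers, and the GO planting targets the
#' planted worker-biased genes.
#'
#' @param config a [sim_config()] object.
#' @param dir output directory (created if missing).
#' @return invisibly, a list with the in-memory objects (`models`,
#'   `tes`, `copies`, `expr`, `go`, `tree`, `traits`) and `files` (named
#'   vector of emitted paths).
#' @export
simulate_all <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(f) file.path(dir, f)

  models <- simulate_gene_models(config)
  expr <- simulate_expression(models, config)
  gene_class <- stats::setNames(expr$truth$true_class, expr$truth$gene_id)
  tes <- simulate_te_callsets(models, config, gene_class = gene_class)
  copies <- evolve_te_copies(2000, 200, config)
  planted_genes <- expr$truth$gene_id[expr$truth$true_class ==
                                        "worker_nymph"]
  go <- simulate_go(models, config, planted_genes = planted_genes)
  tree <- simulate_species_tree(config$n_species,
                                stage_seed(config$seed, "tree"))
  traits <- simulate_bm_traits(tree, config$trait_rho, config$trait_sigma,
                               stage_seed(config$seed, "traits"))

  files <- c(genes = path("genes.gff3"))
  write_gff3(models, files["genes"])
  for (tool in names(tes$callsets)) {
    f <- path(sprintf("te_calls_%s.bed", tool))
    write_te_bed(tes$callsets[[tool]], f, name_col = "tool",
                 extra_col = "superfamily")
    files[paste0("calls_", tool)] <- f
  }
  files["mapped"] <- path("te_mapped.bed")
  write_te_bed(tes$mapped, files["mapped"], name_col = "copy_id",
               extra_col = "superfamily")
  files["copies"] <- path("te_copies.tsv")
  write_tsv(copies, files["copies"])
  files["counts"] <- path("counts.tsv")
  write_tsv(expr$counts, files["counts"], row_names = TRUE)
  files["samples"] <- path("samples.tsv")
  write_tsv(expr$samples, files["samples"])
  files["go_edges"] <- path("go_edges.tsv")
  write_tsv(go$edges, files["go_edges"])
  files["gene2go"] <- path("gene2go.tsv")
  write_tsv(go$annotations, files["gene2go"])
  files["tree"] <- path("tree.nwk")
  ape::write.tree(tree, files["tree"])
  files["traits"] <- path("traits.tsv")
  write_tsv(traits, files["traits"])
  files["truth_te"] <- path("truth_te.tsv")
  write_tsv(tes$truth, files["truth_te"])
  files["truth_bias"] <- path("truth_bias.tsv")
  write_tsv(expr$truth, files["truth_bias"])
  files["truth_go"] <- path("truth_go.tsv")
  write_tsv(data.frame(term_id = go$truth), files["truth_go"])
  files["truth_traits"] <- path("truth_traits.tsv")
  write_tsv(data.frame(parameter = c("rho", "sigma"),
                       value = c(config$trait_rho, config$trait_sigma)),
            files["truth_traits"])

  invisible(list(models = models, tes = tes, copies = copies, expr = expr,
                 go = go, tree = tree, traits = traits, files = files))
}
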