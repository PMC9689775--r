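test_that("simulate_all is byte-deterministic for a fixed config", {
  cfg <- tiny_config()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- simulate_all(cfg, d1)$files
  f2 <- simulate_all(cfg, d2)$files
  expect_identical(basename(f1), basename(f2))
  for (k in names(f1))
    expect_identical(unname(tools::md5sum(f1[[k]])),
                     unname(tools::md5sum(f2[[k]])), label = k)
})

test_that("empty gene set is valid and survives a GFF3 round trip", {
  cfg <- tiny_config(n_genes = 0)
  gm <- simulate_gene_models(cfg)
  expect_equal(nrow(gm$genes), 0)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gm, path)
  expect_match(readLines(path)[1], "gff-version 3")
})

test_that("gene placement is non-overlapping with exons nested in genes", {
  cfg <- sim_config(seed = 7, n_chroms = 1, chrom_length = 1e6,
                    n_genes = 50)
  gm <- simulate_gene_models(cfg)
  expect_equal(nrow(gm$genes), 50)
  # exhaustive containment scan
  for (i in seq_len(nrow(gm$exons))) {
    g <- gm$genes[gm$genes$gene_id == gm$exons$gene_id[i], ]
    expect_true(gm$exons$start[i] >= g$start && gm$exons$end[i] <= g$end)
  }
  # exhaustive pairwise gene-overlap scan
  g <- gm$genes[order(gm$genes$start), ]
  expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  expect_true(all(table(gm$exons$gene_id) >= 1))
  # a genome that cannot hold the genes errors out
  expect_error(simulate_gene_models(
    sim_config(seed = 1, n_chroms = 1, chrom_length = 2e4, n_genes = 100)),
    "genome too small")
})

test_that("GFF3 round trip preserves gene models", {
  gm <- simulate_gene_models(tiny_config())
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gm, path)
  back <- read_gff3(path)
  expect_equal(back$genes[c("chrom", "start", "end", "strand", "gene_id")],
               gm$genes[c("chrom", "start", "end", "strand", "gene_id")])
  expect_equal(nrow(back$exons), nrow(gm$exons))
})

test_that("no-noise call sets have exactly one call per true TE", {
  cfg <- tiny_config(redundancy = 0, fp_rate = 0)
  gm <- simulate_gene_models(cfg)
  sim <- simulate_te_callsets(gm, cfg)
  all_calls <- do.call(rbind, sim$callsets)
  expect_equal(nrow(all_calls), nrow(sim$truth))
  expect_setequal(all_calls$te_id, sim$truth$te_id)
})

test_that("full redundancy with no jitter duplicates every call identically", {
  cfg <- tiny_config(redundancy = 1, jitter_sd = 0, fp_rate = 0)
  gm <- simulate_gene_models(cfg)
  sim <- simulate_te_callsets(gm, cfg)
  key <- function(d) paste(d$chrom, d$start, d$end, d$strand)
  for (cs in sim$callsets)
    expect_setequal(key(cs), key(sim$truth))
  # dedup of the pooled identical call sets collapses to the same library
  # as dedup of a single tool's calls (true TEs may themselves overlap)
  merged <- dedup_calls(do.call(rbind, sim$callsets))
  single <- dedup_calls(sim$callsets[[1]])
  expect_setequal(key(merged), key(single))
  expect_equal(nrow(merged), nrow(single))
})

test_that("per-class insertion multipliers double the within-class density", {
  cfg <- sim_config(seed = 3, n_chroms = 2, chrom_length = 2e6,
                    n_genes = 400, te_density = 120,
                    te_bias_mult = c(none = 1, worker_nymph = 2,
                                     queen_female = 1))
  gm <- simulate_gene_models(cfg)
  cls <- setNames(rep(c("worker_nymph", "none"), length.out = 400),
                  gm$genes$gene_id)
  sim <- simulate_te_callsets(gm, cfg, gene_class = cls)
  # counting oracle on the truth table: TE midpoints per gene class
  mid <- (sim$truth$start + sim$truth$end) / 2
  g <- gm$genes
  host <- rep(NA_character_, nrow(sim$truth))
  for (i in seq_len(nrow(g))) {
    ing <- sim$truth$chrom == g$chrom[i] & mid >= g$start[i] & mid <= g$end[i]
    host[ing] <- cls[[g$gene_id[i]]]
  }
  mb <- tapply(g$end - g$start + 1, cls[g$gene_id], sum) / 1e6
  dens <- table(factor(host, c("none", "worker_nymph"))) / mb[c("none", "worker_nymph")]
  ratio <- dens[["worker_nymph"]] / dens[["none"]]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.6)
})

test_that("evolved copies honour the divergence limits", {
  cfg0 <- tiny_config(k_true = 0)
  aln <- evolve_te_copies(300, 5, cfg0)
  expect_true(all(aln$copy_aln == aln$consensus_aln[1]))
  # near-infinite kappa: transversions vanish
  cfgk <- tiny_config(k_true = 0.2, kappa = 1e7)
  aln <- evolve_te_copies(2000, 20, cfgk)
  dv <- divergence_table(aln, cpg_correct = FALSE)
  expect_lt(max(dv$q), 0.003)
  expect_gt(mean(dv$p), 0.05)
  expect_error(evolve_te_copies(500, 2, tiny_config(k_true = 4)),
               "divergence out of range")
})

test_that("negative-binomial draws match the requested moments", {
  set.seed(99)
  x <- rnb_counts(10000, mu = 50, dispersion = 0.3)
  target_var <- 50 + 0.3 * 50^2
  se_mean <- sqrt(target_var / 10000)
  expect_lt(abs(mean(x) - 50), 3 * se_mean)
  expect_lt(abs(var(x) / target_var - 1), 0.1)
  y <- rnb_counts(10000, mu = 20, dispersion = 0)   # Poisson limit
  expect_lt(abs(var(y) / 20 - 1), 0.1)
})

test_that("planted expression effects appear at the configured fold change", {
  cfg <- tiny_config(planted_lfc = 0)
  gm <- simulate_gene_models(cfg)
  expect_true(all(simulate_expression(gm, cfg)$truth$true_class == "none"))

  cfg <- tiny_config(nb_dispersion = 0, planted_lfc = 3,
                     n_libs_per_group = 20)
  ex <- simulate_expression(gm, cfg)
  q <- ex$samples$group == "queen_female"
  ratio <- rowMeans(ex$counts[, q]) / rowMeans(ex$counts[, !q])
  up <- ex$truth$true_class == "queen_female"
  expect_lt(abs(mean(ratio[up]) / 2^3 - 1), 0.25)
  expect_lt(abs(mean(ratio[ex$truth$true_class == "none"]) - 1), 0.15)
})

test_that("simulated GO DAG is closed, acyclic and star-shaped at depth 1", {
  cfg <- tiny_config()
  gm <- simulate_gene_models(cfg)
  go <- simulate_go(gm, cfg)
  dag <- go$dag                     # construction validates acyclicity
  # closure: every annotated gene reaches the root's gene set
  root <- dag$terms[lengths(dag$parents[dag$terms]) == 0]
  expect_length(root, 1)
  expect_setequal(dag$genes[[root]], unique(go$annotations$gene_id))
  # each raw annotation is propagated to all ancestors
  for (i in sample(nrow(go$annotations), 20)) {
    tid <- go$annotations$term_id[i]
    gid <- go$annotations$gene_id[i]
    for (anc in dag$ancestors[[tid]])
      expect_true(gid %in% dag$genes[[anc]])
  }
  star <- simulate_go(gm, tiny_config(go_depth = 1))
  expect_true(all(star$edges$parent == star$edges$parent[1]))
})

test_that("Brownian traits behave at the correlation extremes", {
  tr <- simulate_species_tree(16, 5)
  t1 <- simulate_bm_traits(tr, rho = 1, sigma = 1, seed = 9)
  c1 <- pic_contrasts(tr, setNames(t1$trait1, t1$species))
  c2 <- pic_contrasts(tr, setNames(t1$trait2, t1$species))
  expect_equal(unname(c1), unname(c2), tolerance = 1e-10)
  t0 <- simulate_bm_traits(tr, rho = 0.3, sigma = 0, seed = 9)
  expect_true(all(t0$trait1 == 0 & t0$trait2 == 0))
  bad <- tr; bad$edge.length[2] <- 0
  expect_error(simulate_bm_traits(bad, 0.5, 1, 1), "zero-length")
})
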