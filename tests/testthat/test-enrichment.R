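# small hand-built DAG:  root -> {m1, m2}; m1 -> {leafA, leafB}; m2 -> leafB
toy_dag <- function(genes_per_term = list(
                      leafA = paste0("g", 1:10),
                      leafB = paste0("g", 11:20),
                      m2 = paste0("g", 21:25))) {
  edges <- data.frame(child = c("m1", "m2", "leafA", "leafB", "leafB"),
                      parent = c("root", "root", "m1", "m1", "m2"))
  ann <- do.call(rbind, lapply(names(genes_per_term), function(t)
    data.frame(gene_id = genes_per_term[[t]], term_id = t)))
  go_dag(edges, ann)
}

test_that("go_dag validates, closes annotations and measures depth", {
  dag <- toy_dag()
  expect_equal(unname(dag$depth[c("root", "m1", "leafA")]), c(0L, 1L, 2L))
  # closure: root sees every annotated gene, m1 sees both leaves
  expect_setequal(dag$genes$root, paste0("g", 1:25))
  expect_setequal(dag$genes$m1, paste0("g", 1:20))
  expect_setequal(dag$genes$leafB, paste0("g", 11:20))
  # leafB has two ancestor paths
  expect_setequal(dag$ancestors$leafB, c("m1", "m2", "root"))
  expect_error(go_dag(data.frame(child = c("a", "b"), parent = c("b", "a")),
                      data.frame(gene_id = "g", term_id = "a")),
               "cycle")
})

test_that("gene scores follow the focal/opposite/neutral scheme", {
  rec <- classify_bias(data.frame(
    gene_id = c("w", "q", "n"), log2fc = c(-2, 3, 0.1),
    pvalue = c(1e-4, 1e-4, 0.5), padj = c(0.001, 0.001, 0.8)))
  s <- bias_gene_scores(rec, focal_stage = "worker_nymph")
  expect_equal(s$score[s$gene_id == "w"], 3)            # -log10(0.001)
  expect_equal(s$score[s$gene_id == "q"], 0)            # opposite: padj -> 1
  expect_equal(s$score[s$gene_id == "n"], -log10(0.8))
  expect_equal(s$significant, c(TRUE, FALSE, FALSE))
  s1 <- bias_gene_scores(rec, "worker_nymph", opposite = "score_one")
  expect_equal(s1$score[s1$gene_id == "q"], 1)
  # padj = 1 scores 0; untested genes are dropped with a message
  rec2 <- data.frame(gene_id = c("a", "b"), log2fc = c(1, 1),
                     pvalue = c(1, NA), padj = c(1, NA))
  expect_message(s2 <- bias_gene_scores(classify_bias(rec2), "queen_female"),
                 "discarding")
  expect_equal(s2$score, 0)

  prof <- data.frame(gene_id = c("a", "b"), rate = c(1.5, 0),
                     te_rich = c(TRUE, FALSE))
  ts <- te_gene_scores(prof)
  expect_equal(ts$score, c(1.5, 0))
  expect_equal(ts$significant, c(TRUE, FALSE))
  expect_equal(nrow(te_gene_scores(prof[0, ])), 0)
})

test_that("ks_term_test behaves at the null, separation and degeneracy", {
  set.seed(1)
  # exchangeable scores: p not systematically small
  ps <- replicate(200, {
    x <- rnorm(60)
    ks_term_test(x[1:15], x[16:60])
  })
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps < 0.05), 0.12)
  # complete separation: p near its minimum
  expect_lt(ks_term_test(101:160, 1:100), 1e-6)
  # wrong-direction separation is not significant
  expect_gt(ks_term_test(1:50, 101:200), 0.5)
  # degenerate: term covers the whole universe
  expect_equal(ks_term_test(rnorm(10), numeric(0)), 1)
})

test_that("elim on an edge-free DAG equals classical per-term testing", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:120)
  ann <- data.frame(gene_id = sample(genes, 300, TRUE),
                    term_id = sample(sprintf("T%02d", 1:15), 300, TRUE))
  dag <- go_dag(data.frame(child = character(), parent = character()), ann)
  scores <- data.frame(gene_id = genes, score = rnorm(120),
                       significant = FALSE)
  res <- elim_enrichment(dag, scores, elim_cutoff = 0.5)
  for (i in seq_len(nrow(res))) {
    tg <- intersect(dag$genes[[res$term_id[i]]], genes)
    p_classic <- ks_term_test(scores$score[match(tg, scores$gene_id)],
                              scores$score[match(setdiff(genes, tg),
                                                 scores$gene_id)])
    expect_equal(res$pvalue[i], p_classic)
  }
  # elim_cutoff = 0 also reduces to classical testing on any DAG
  dag2 <- toy_dag()
  sc2 <- data.frame(gene_id = paste0("g", 1:25),
                    score = c(rep(5, 10), rep(0, 15)) + rnorm(25, 0, 0.1),
                    significant = rep(c(TRUE, FALSE), c(10, 15)))
  r0 <- elim_enrichment(dag2, sc2, elim_cutoff = 0)
  for (i in seq_len(nrow(r0))) {
    tg <- intersect(dag2$genes[[r0$term_id[i]]], sc2$gene_id)
    expect_equal(r0$pvalue[i],
                 ks_term_test(sc2$score[match(tg, sc2$gene_id)],
                              sc2$score[setdiff(seq_len(25),
                                                match(tg, sc2$gene_id))]))
  }
})

test_that("elim localizes a planted signal to the specific term", {
  set.seed(7)
  # leafA's genes carry high scores; its parent m1 inherits them only
  # through leafA and is de-enriched once leafA's genes are eliminated
  dag <- toy_dag(genes_per_term = list(
    leafA = paste0("g", 1:12),
    leafB = paste0("g", 13:40),
    m2 = paste0("g", 41:60)))
  genes <- paste0("g", 1:80)
  score <- c(rnorm(12, 6, 0.5), rnorm(68, 0, 1))
  scores <- data.frame(gene_id = genes, score = score,
                       significant = score > 3)
  res <- elim_enrichment(dag, scores, elim_cutoff = 0.01)
  p <- setNames(res$pvalue, res$term_id)
  expect_lt(p[["leafA"]], 0.05)
  expect_gt(p[["m1"]], 0.05)      # signal eliminated from the ancestor
  expect_gt(p[["root"]], 0.05)
  # without elimination the ancestor would look enriched too
  res0 <- elim_enrichment(dag, scores, elim_cutoff = 0)
  p0 <- setNames(res0$pvalue, res0$term_id)
  expect_lt(p0[["m1"]], 0.05)
})

test_that("the specificity cascade removes terms by the three criteria", {
  primary <- data.frame(term_id = c("T1", "T2", "T3", "T4"),
                        pvalue = c(0.001, 0.002, 0.003, 0.004))
  comp <- rbind(
    # criterion 1 for T2: DEG enrichment at the same stage, BOTH socials
    data.frame(term_id = "T2", pvalue = 0.01, social = "eusocial",
               stage = "worker_nymph", te_rich = FALSE),
    data.frame(term_id = "T2", pvalue = 0.01, social = "gregarious",
               stage = "worker_nymph", te_rich = FALSE),
    # only one social level for T1: not removed
    data.frame(term_id = "T1", pvalue = 0.01, social = "gregarious",
               stage = "worker_nymph", te_rich = FALSE),
    # criterion 2 for T3: TE-rich, same stage, other social
    data.frame(term_id = "T3", pvalue = 0.02, social = "gregarious",
               stage = "worker_nymph", te_rich = TRUE),
    # criterion 3 for T4: TE-rich, same social, different stage (no bias)
    data.frame(term_id = "T4", pvalue = 0.01, social = "eusocial",
               stage = "none", te_rich = TRUE),
    # non-significant comparisons never trigger removal
    data.frame(term_id = "T1", pvalue = 0.4, social = "gregarious",
               stage = "worker_nymph", te_rich = TRUE))
  out <- specificity_filter(primary, comp, social = "eusocial",
                            stage = "worker_nymph")
  expect_equal(out$removal_reason,
               c("none", "criterion1", "criterion2", "criterion3"))
  expect_equal(out$survived_specificity, c(TRUE, FALSE, FALSE, FALSE))
  # empty comparison set removes nothing; output is always a subset
  keep <- specificity_filter(primary, comp[0, ], "eusocial", "worker_nymph")
  expect_true(all(keep$survived_specificity))
  expect_true(all(out$term_id %in% primary$term_id))
})

test_that("criteria are recorded in priority order", {
  primary <- data.frame(term_id = "T", pvalue = 0.001)
  comp <- rbind(
    data.frame(term_id = "T", pvalue = 0.01, social = "eusocial",
               stage = "worker_nymph", te_rich = FALSE),
    data.frame(term_id = "T", pvalue = 0.01, social = "gregarious",
               stage = "worker_nymph", te_rich = FALSE),
    data.frame(term_id = "T", pvalue = 0.01, social = "gregarious",
               stage = "worker_nymph", te_rich = TRUE))
  out <- specificity_filter(primary, comp, "eusocial", "worker_nymph")
  expect_equal(out$removal_reason, "criterion1")   # 1 outranks 2
})
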