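test_that("closest_te honours the same-strand rule and distances", {
  gm <- two_gene_models()
  tes <- data.frame(chrom = "chr1",
                    start = c(1500, 3100, 3500, 7000),
                    end = c(1600, 3200, 3600, 7100),
                    strand = c("+", "-", "+", "-"),
                    copy_id = c("in_gene", "opp_near", "same_far", "b_near"))
  cl <- closest_te(gm, tes)
  # overlapping same-strand TE: distance 0
  expect_equal(cl$closest_te_id[cl$gene_id == "geneA"], "in_gene")
  expect_equal(cl$closest_distance[cl$gene_id == "geneA"], 0)
  # geneB (-): the 100 bp-away + TE is ignored in favour of the - TE
  expect_equal(cl$closest_te_id[cl$gene_id == "geneB"], "b_near")
  expect_equal(cl$closest_distance[cl$gene_id == "geneB"], 1000)
  # without the strand rule the nearer opposite-strand TE wins for geneA
  cl2 <- closest_te(gm, tes[tes$copy_id != "in_gene", ], same_strand = FALSE)
  expect_equal(cl2$closest_te_id[cl2$gene_id == "geneA"], "opp_near")
  # no candidate at all: null record
  none <- closest_te(gm, tes[tes$strand == "-" & tes$start > 6500, ][0, ])
  expect_true(all(is.na(none$closest_te_id)))
})

test_that("closest_te matches the all-pairs oracle on random instances", {
  for (seed in 1:40) {
    set.seed(2000 + seed)
    inst <- random_gene_te_instance(sample(2:40, 1), sample(1:150, 1))
    for (ss in c(TRUE, FALSE)) {
      got <- closest_te(inst$genes, inst$tes, same_strand = ss)
      want <- oracle_closest(inst$genes, inst$tes, same_strand = ss)
      expect_equal(got, want, label = sprintf("seed %d ss %s", seed, ss))
    }
  }
})

test_that("profile_genes counts insertions with exon precedence", {
  gm <- two_gene_models()
  tes <- data.frame(chrom = "chr1",
                    start = c(1100, 1500, 2550, 5200, 5300),
                    end = c(1300, 1700, 2700, 5400, 5350),
                    strand = c("+", "+", "+", "-", "+"),
                    copy_id = paste0("te", 1:5))
  de <- data.frame(gene_id = c("geneA", "geneB"),
                   bias_class = c("worker_nymph", "none"))
  prof <- profile_genes(gm, tes, de)
  a <- prof[prof$gene_id == "geneA", ]
  # te1 straddles exon1 boundary -> exonic; te2 intronic; te3 straddles
  # the intron/exon2 boundary -> exonic
  expect_equal(c(a$n_te, a$n_exonic, a$n_intronic), c(3, 2, 1))
  expect_equal(a$rate, 3 / 2)          # 3 TEs in a 2 kb gene
  b <- prof[prof$gene_id == "geneB", ]
  expect_equal(c(b$n_te, b$n_exonic), c(1, 1))  # + TE ignored on - gene
  expect_equal(prof$bias_class, c("worker_nymph", "none"))
  # invariant: n_te = n_exonic + n_intronic
  expect_equal(prof$n_te, prof$n_exonic + prof$n_intronic)
})

test_that("a TE overlapping two genes counts in both profiles", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 2001),
                      end = c(2000, 3000), strand = "+",
                      gene_id = c("g1", "g2"))
  exons <- transform(genes, exon_id = paste0(gene_id, ".e1"))
  gm <- gene_models(genes, exons)
  te <- data.frame(chrom = "chr1", start = 1900, end = 2100, strand = "+",
                   copy_id = "bridge")
  prof <- profile_genes(gm, te)
  expect_equal(prof$n_te, c(1, 1))
})

test_that("conservation: within-gene plus intergenic TEs account for all", {
  set.seed(77)
  inst <- random_gene_te_instance(30, 120)
  exons <- transform(inst$genes, exon_id = paste0(gene_id, ".e1"))
  gm <- gene_models(inst$genes, exons)
  prof <- profile_genes(gm, inst$tes)
  ann <- annotate_tes(gm, inst$tes)
  # brute-force multiplicity-counted overlaps and per-TE gene status
  cnt <- 0
  hit <- logical(nrow(inst$tes))
  for (j in seq_len(nrow(inst$tes))) for (i in seq_len(nrow(inst$genes))) {
    if (inst$tes$chrom[j] != inst$genes$chrom[i]) next
    if (inst$tes$strand[j] != inst$genes$strand[i]) next
    if (inst$tes$start[j] <= inst$genes$end[i] &&
        inst$tes$end[j] >= inst$genes$start[i]) {
      cnt <- cnt + 1
      hit[j] <- TRUE
    }
  }
  expect_equal(sum(prof$n_te), cnt)
  expect_equal(ann$in_gene, hit)
  expect_equal(sum(!ann$in_gene), nrow(inst$tes) - sum(hit))
})

test_that("flag_te_rich uses a strict Q3 threshold", {
  p <- data.frame(gene_id = letters[1:4], rate = c(0, 0, 1, 3))
  f <- flag_te_rich(p)
  expect_equal(attr(f, "q3"), 1.5)      # type-7 linear interpolation
  expect_equal(f$te_rich, c(FALSE, FALSE, FALSE, TRUE))
  # all equal rates: nothing is TE-rich
  eq <- flag_te_rich(data.frame(gene_id = letters[1:5], rate = rep(2, 5)))
  expect_false(any(eq$te_rich))
  # single gene: its own rate is Q3, strict > fails
  one <- flag_te_rich(data.frame(gene_id = "a", rate = 4))
  expect_false(one$te_rich)
  # subset scoping: Q3 from the subset only, others stay NA
  sub <- flag_te_rich(p, subset = p$rate > 0)
  expect_true(is.na(sub$te_rich[1]))
  expect_equal(sub$te_rich[3:4], c(FALSE, TRUE))
  # at most ceiling(25%) of the evaluation set is flagged (up to ties)
  set.seed(5)
  big <- data.frame(gene_id = sprintf("g%d", 1:200), rate = rexp(200))
  expect_lte(sum(flag_te_rich(big)$te_rich), ceiling(0.25 * 200))
})

test_that("build_tables produces complete zero-filled factorial designs", {
  gm <- two_gene_models()
  tes <- data.frame(chrom = "chr1", start = c(1100, 5200, 9000),
                    end = c(1300, 5400, 9100), strand = c("+", "-", "+"),
                    superfamily = c("LINE", "Gypsy", "hAT"),
                    copy_id = paste0("te", 1:3))
  de <- data.frame(gene_id = c("geneA", "geneB"),
                   bias_class = c("worker_nymph", "none"))
  prof <- profile_genes(gm, tes, de)
  prof$species <- "spA"
  ann <- annotate_tes(gm, tes, de)
  ann$species <- "spA"
  meta <- data.frame(species = "spA", social_level = "eusocial")
  tabs <- build_tables(prof, ann, meta)
  expect_named(tabs, c("gene_te", "gene_feature", "te_gene", "te_deg"))
  gt <- tabs$gene_te
  expect_equal(nrow(gt), 6)                     # 3 bias x 2 overlap
  expect_equal(sum(gt$count), 2)                # both genes tested
  expect_equal(sum(gt$count[gt$te_overlap == "yes"]), 2)
  tg <- tabs$te_gene
  expect_equal(nrow(tg), 8)                     # 4 superfamilies x 2
  expect_equal(sum(tg$count), 3)                # every retained TE counted
  expect_equal(sum(tg$count[tg$gene_overlap == "yes"]), 2)
  td <- tabs$te_deg
  expect_equal(sum(td$count), 2)                # only in-gene TEs
})

test_that("untested genes are excluded from the factorial tables", {
  gm <- two_gene_models()
  tes <- data.frame(chrom = "chr1", start = 1100, end = 1300, strand = "+",
                    superfamily = "LINE", copy_id = "te1")
  de <- data.frame(gene_id = c("geneA", "geneB"),
                   bias_class = c("untested", "none"))
  prof <- profile_genes(gm, tes, de); prof$species <- "s"
  ann <- annotate_tes(gm, tes, de); ann$species <- "s"
  tabs <- build_tables(prof, ann,
                       data.frame(species = "s", social_level = "gregarious"))
  expect_equal(sum(tabs$gene_te$count), 1)      # geneA dropped
  expect_equal(sum(tabs$te_deg$count), 0)       # its TE dropped too
})

test_that("gene-length summaries report t confidence intervals", {
  p <- data.frame(gene_id = c("a", "b", "c"),
                  gene_length = c(1000, 3000, 500),
                  bias_class = c("none", "none", "worker_nymph"))
  s <- summarize_gene_length(p)
  none <- s[s$bias_class == "none", ]
  expect_equal(none$mean_length, 2000)
  expect_false(none$degenerate)
  expect_equal(none$ci_high - none$mean_length,
               qt(0.975, 1) * sd(c(1000, 3000)) / sqrt(2))
  expect_true(s$degenerate[s$bias_class == "worker_nymph"])
  # coverage under normal sampling
  set.seed(12)
  hits <- 0
  for (r in 1:300) {
    x <- data.frame(gene_id = 1:20, gene_length = rnorm(20, 5000, 800),
                    bias_class = "none")
    ci <- summarize_gene_length(x)
    hits <- hits + (ci$ci_low <= 5000 && 5000 <= ci$ci_high)
  }
  expect_gt(hits / 300, 0.90)
  expect_lt(hits / 300, 0.99)
})
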