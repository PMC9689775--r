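# Independent brute-force oracles, written with plain loops and arithmetic
# so they share no machinery with the package implementations.

# Exhaustive pairwise dedup check in the documented priority order:
# length filter first, then sweep longest-first (ties: earlier start, then
# tool), dropping a call that overlaps any kept same-chrom/strand call by
# more than `max_frac` of the shorter length.
oracle_dedup <- function(calls, max_frac = 0.2, max_len = 10000) {
  len <- calls$end - calls$start + 1
  calls <- calls[len <= max_len, , drop = FALSE]
  if (!nrow(calls)) return(calls)
  len <- calls$end - calls$start + 1
  ord <- order(-len, calls$start, calls$tool, calls$chrom, calls$end)
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (calls$chrom[i] != calls$chrom[j]) next
      if (calls$strand[i] != calls$strand[j]) next
      ov <- min(calls$end[i], calls$end[j]) -
        max(calls$start[i], calls$start[j]) + 1
      if (ov <= 0) next
      if (ov / min(len[i], len[j]) > max_frac) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- calls[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$tool), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All-pairs closest-TE scan; distance 0 iff >=1 bp overlap, else the
# bedtools-style 1 + gap convention.
oracle_closest <- function(genes, tes, same_strand = TRUE) {
  res <- data.frame(gene_id = genes$gene_id,
                    closest_te_id = NA_character_,
                    closest_distance = NA_real_)
  for (i in seq_len(nrow(genes))) {
    best_d <- Inf; best_start <- Inf; best_id <- NA_character_
    for (j in seq_len(nrow(tes))) {
      if (tes$chrom[j] != genes$chrom[i]) next
      if (same_strand && tes$strand[j] != genes$strand[i]) next
      d <- max(0, tes$start[j] - genes$end[i], genes$start[i] - tes$end[j])
      better <- d < best_d ||
        (d == best_d && (tes$start[j] < best_start ||
           (tes$start[j] == best_start && tes$copy_id[j] < best_id)))
      if (better) {
        best_d <- d; best_start <- tes$start[j]; best_id <- tes$copy_id[j]
      }
    }
    if (is.finite(best_d)) {
      res$closest_te_id[i] <- best_id
      res$closest_distance[i] <- best_d
    }
  }
  res
}

# Recursive Felsenstein pruning, structured as plain tree recursion over
# the edge matrix rather than a postorder sweep.
oracle_pic <- function(tree, trait) {
  n_tip <- length(tree$tip.label)
  kids <- function(node) tree$edge[tree$edge[, 1] == node, 2]
  elen <- function(node) tree$edge.length[tree$edge[, 2] == node]
  contrasts <- c()
  prune <- function(node) {
    if (node <= n_tip)
      return(list(x = trait[[tree$tip.label[node]]], v = 0))
    ch <- kids(node)
    a <- prune(ch[1]); b <- prune(ch[2])
    va <- a$v + elen(ch[1]); vb <- b$v + elen(ch[2])
    contrasts[as.character(node)] <<- (a$x - b$x) / sqrt(va + vb)
    list(x = (a$x / va + b$x / vb) / (1 / va + 1 / vb),
         v = va * vb / (va + vb))
  }
  prune(n_tip + 1L)
  contrasts[order(as.integer(names(contrasts)))]
}

# Random interval instances for the oracle-equivalence suites.
random_calls <- function(n, n_chrom = 2, span = 3000, max_te_len = 1200) {
  start <- sample.int(span, n, replace = TRUE)
  len <- sample.int(max_te_len, n, replace = TRUE)
  data.frame(chrom = sprintf("chr%d", sample.int(n_chrom, n, TRUE)),
             start = start, end = start + len - 1L,
             strand = sample(c("+", "-"), n, TRUE),
             tool = sprintf("t%02d", sample.int(5, n, TRUE)))
}

random_gene_te_instance <- function(n_genes, n_tes, span = 50000) {
  gs <- sort(sample.int(span, n_genes))
  genes <- data.frame(chrom = sample(c("chrA", "chrB"), n_genes, TRUE),
                      start = gs,
                      end = gs + sample.int(2000, n_genes, TRUE),
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      gene_id = sprintf("g%03d", seq_len(n_genes)))
  ts <- sample.int(span, n_tes, replace = TRUE)
  tes <- data.frame(chrom = sample(c("chrA", "chrB"), n_tes, TRUE),
                    start = ts,
                    end = ts + sample.int(800, n_tes, TRUE),
                    strand = sample(c("+", "-"), n_tes, TRUE),
                    copy_id = sprintf("te%03d", seq_len(n_tes)))
  list(genes = genes, tes = tes)
}
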