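#' Closest TE per gene (same strand)
#'
#' For each gene, finds the closest TE copy in the bedtools-closest
#' sense: distance 0 if and only if the TE overlaps the gene span by at
#' least 1 bp, otherwise 1 + the number of bases separating them. By
#' default only TEs on the gene's DNA strand are candidates. Ties are
#' broken deterministically: smaller distance, then lower TE start
#' coordinate, then lexicographic `copy_id`. Genes with no candidate TE
#' get an `NA` record.
#'
#' @param genes a `gene_models` object or a gene data frame
#'   (`chrom,start,end,strand,gene_id`).
#' @param tes mapped-TE data frame (`chrom,start,end,strand,copy_id`).
#' @param same_strand restrict candidates to the gene's strand?
#' @return data frame `gene_id, closest_te_id, closest_distance`.
#' @export
closest_te <- function(genes, tes, same_strand = TRUE) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  out <- data.frame(gene_id = g$gene_id,
                    closest_te_id = NA_character_,
                    closest_distance = NA_real_)
  if (!nrow(g) || !nrow(tes)) return(out)
  if (!"copy_id" %in% names(tes))
    tes$copy_id <- sprintf("row%d", seq_len(nrow(tes)))
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                 strand = g$strand)
  gr_t <- GenomicRanges::GRanges(tes$chrom,
                                 IRanges::IRanges(tes$start, tes$end),
                                 strand = tes$strand)
  pick_best <- function(cand_idx, dist) {
    o <- order(dist, tes$start[cand_idx], tes$copy_id[cand_idx])[1]
    c(cand_idx[o], dist[o])
  }
  strands <- if (same_strand) c("+", "-") else "*"
  for (s in strands) {
    gi <- if (s == "*") seq_len(nrow(g)) else which(g$strand == s)
    ti <- if (s == "*") seq_len(nrow(tes)) else which(tes$strand == s)
    if (!length(gi) || !length(ti)) next
    gg <- gr_g[gi]; tt <- gr_t[ti]
    ov <- GenomicRanges::findOverlaps(gg, tt, ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (k in unique(qh)) {
      cand <- ti[sh[qh == k]]
      best <- pick_best(cand, rep(0, length(cand)))
      out$closest_te_id[gi[k]] <- tes$copy_id[best[1]]
      out$closest_distance[gi[k]] <- 0
    }
    rest <- setdiff(seq_along(gi), unique(qh))
    if (length(rest)) {
      nr <- GenomicRanges::nearest(gg[rest], tt, select = "all",
                                   ignore.strand = TRUE)
      qh2 <- S4Vectors::queryHits(nr); sh2 <- S4Vectors::subjectHits(nr)
      d <- GenomicRanges::distance(gg[rest][qh2], tt[sh2],
                                   ignore.strand = TRUE) + 1
      for (k in unique(qh2)) {
        sel <- qh2 == k
        best <- pick_best(ti[sh2[sel]], d[sel])
        out$closest_te_id[gi[rest[k]]] <- tes$copy_id[best[1]]
        out$closest_distance[gi[rest[k]]] <- best[2]
      }
    }
  }
  out
}

#' Per-gene TE insertion profiles
#'
#' A TE copy counts as inserted "within" a gene when it overlaps the gene
#' span by at least 1 bp on the same strand (configurable). An insertion
#' is exonic when it overlaps any exon of that gene by at least 1 bp
#' (boundary-straddling TEs take exon precedence), otherwise intronic.
#' The insertion rate is TEs per gene kilobase. A TE overlapping several
#' genes is counted in each gene's profile.
#'
#' @param genes a `gene_models` object.
#' @param tes mapped-TE data frame (`chrom,start,end,strand,copy_id`).
#' @param de_records optional DE table with `gene_id` and `bias_class`
#'   (genes absent from it are marked `untested`).
#' @param same_strand require TE and gene on the same strand?
#' @return data frame of class `gene_te_profile`: `gene_id, gene_length,
#'   bias_class, n_te, n_exonic, n_intronic, rate, te_rich,
#'   closest_te_id, closest_distance`.
#' @export
profile_genes <- function(genes, tes, de_records = NULL,
                          same_strand = TRUE) {
  stopifnot(inherits(genes, "gene_models"))
  g <- genes$genes
  if (!"copy_id" %in% names(tes) && nrow(tes))
    tes$copy_id <- sprintf("row%d", seq_len(nrow(tes)))
  prof <- data.frame(gene_id = g$gene_id,
                     gene_length = g$end - g$start + 1,
                     bias_class = "untested",
                     n_te = 0L, n_exonic = 0L, n_intronic = 0L)
  if (nrow(g) && nrow(tes)) {
    gr_g <- GenomicRanges::GRanges(g$chrom,
                                   IRanges::IRanges(g$start, g$end),
                                   strand = g$strand)
    gr_t <- GenomicRanges::GRanges(tes$chrom,
                                   IRanges::IRanges(tes$start, tes$end),
                                   strand = tes$strand)
    ov <- GenomicRanges::findOverlaps(gr_t, gr_g,
                                      ignore.strand = !same_strand)
    th <- S4Vectors::queryHits(ov); gh <- S4Vectors::subjectHits(ov)
    if (length(th)) {
      e <- genes$exons
      gr_e <- GenomicRanges::GRanges(e$chrom,
                                     IRanges::IRanges(e$start, e$end),
                                     strand = e$strand)
      ove <- GenomicRanges::findOverlaps(gr_t, gr_e,
                                         ignore.strand = !same_strand)
      exon_pair <- unique(paste(S4Vectors::queryHits(ove),
                                e$gene_id[S4Vectors::subjectHits(ove)]))
      exonic <- paste(th, g$gene_id[gh]) %in% exon_pair
      tab_all <- table(factor(g$gene_id[gh], levels = g$gene_id))
      tab_ex <- table(factor(g$gene_id[gh[exonic]], levels = g$gene_id))
      prof$n_te <- as.integer(tab_all)
      prof$n_exonic <- as.integer(tab_ex)
      prof$n_intronic <- prof$n_te - prof$n_exonic
    }
  }
  prof$rate <- prof$n_te / (prof$gene_length / 1000)
  prof$te_rich <- NA
  if (!is.null(de_records)) {
    i <- match(prof$gene_id, de_records$gene_id)
    cls <- as.character(de_records$bias_class[i])
    cls[is.na(cls)] <- "untested"
    prof$bias_class <- cls
  }
  cl <- closest_te(genes, tes, same_strand = same_strand)
  prof$closest_te_id <- cl$closest_te_id[match(prof$gene_id, cl$gene_id)]
  prof$closest_distance <- cl$closest_distance[match(prof$gene_id,
                                                     cl$gene_id)]
  class(prof) <- c("gene_te_profile", "data.frame")
  prof
}

#' Flag TE-rich genes
#'
#' A gene is TE-rich when its insertion rate (TEs per kilobase) is
#' strictly greater than the third quartile of the rates of the
#' evaluation subset. The quartile uses linear interpolation between
#' order statistics ([stats::quantile()] type 7) by default. Genes
#' outside the subset keep `te_rich = NA`.
#'
#' @param profiles output of [profile_genes()].
#' @param subset logical vector (length `nrow(profiles)`), index vector,
#'   or `NULL` for all genes: the evaluation set over which Q3 is taken.
#' @param qtype quantile algorithm type passed to [stats::quantile()].
#' @return `profiles` with `te_rich` set on the subset; attribute `q3`
#'   records the threshold.
#' @examples
#' p <- data.frame(gene_id = letters[1:4], rate = c(0, 0, 1, 3))
#' flag_te_rich(p)$te_rich  # only the rate-3 gene exceeds Q3 = 1.5
#' @export
flag_te_rich <- function(profiles, subset = NULL, qtype = 7) {
  idx <- if (is.null(subset)) seq_len(nrow(profiles))
         else if (is.logical(subset)) which(subset)
         else as.integer(subset)
  if (!length(idx)) stop("evaluation subset is empty")
  q3 <- stats::quantile(profiles$rate[idx], 0.75, type = qtype,
                        names = FALSE)
  profiles$te_rich <- NA
  profiles$te_rich[idx] <- profiles$rate[idx] > q3
  attr(profiles, "q3") <- q3
  profiles
}

#' Annotate TE copies with their host gene
#'
#' The TE-level complement of [profile_genes()]: for each TE copy,
#' whether it falls within a gene (strand rule as in profiling), the
#' host gene id (largest overlap; ties by lower gene start), the host's
#' bias class, and the exon/intron feature assignment (exon precedence).
#'
#' @inheritParams profile_genes
#' @return `tes` with added columns `in_gene, gene_id, gene_bias,
#'   feature`.
#' @export
annotate_tes <- function(genes, tes, de_records = NULL,
                         same_strand = TRUE) {
  stopifnot(inherits(genes, "gene_models"))
  g <- genes$genes
  tes$in_gene <- FALSE
  tes$gene_id <- NA_character_
  tes$gene_bias <- NA_character_
  tes$feature <- NA_character_
  if (!nrow(tes) || !nrow(g)) return(tes)
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                 strand = g$strand)
  gr_t <- GenomicRanges::GRanges(tes$chrom,
                                 IRanges::IRanges(tes$start, tes$end),
                                 strand = tes$strand)
  ov <- GenomicRanges::findOverlaps(gr_t, gr_g, ignore.strand = !same_strand)
  th <- S4Vectors::queryHits(ov); gh <- S4Vectors::subjectHits(ov)
  if (length(th)) {
    ovw <- pmin(tes$end[th], g$end[gh]) - pmax(tes$start[th], g$start[gh]) + 1
    o <- order(th, -ovw, g$start[gh])
    first <- o[!duplicated(th[o])]
    tes$in_gene[th[first]] <- TRUE
    tes$gene_id[th[first]] <- g$gene_id[gh[first]]
    e <- genes$exons
    gr_e <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                   strand = e$strand)
    ove <- GenomicRanges::findOverlaps(gr_t, gr_e,
                                       ignore.strand = !same_strand)
    exon_pair <- unique(paste(S4Vectors::queryHits(ove),
                              e$gene_id[S4Vectors::subjectHits(ove)]))
    in_idx <- which(tes$in_gene)
    tes$feature[in_idx] <- ifelse(
      paste(in_idx, tes$gene_id[in_idx]) %in% exon_pair, "exon", "intron")
  }
  if (!is.null(de_records)) {
    i <- match(tes$gene_id, de_records$gene_id)
    tes$gene_bias <- as.character(de_records$bias_class[i])
  }
  tes
}

#' Contingency tables for the factorial TE-insertion models
#'
#' Builds the four long-format count tables underlying the factorial
#' analyses, with complete (zero-filled) factor grids:
#'
#' * `gene_te`: genes with/without a TE insertion, by species, social
#'   level and bias class;
#' * `gene_feature`: genes with an insertion, split exon/intron (a gene
#'   with any exonic insertion counts as exon), by species, social
#'   level and bias class;
#' * `te_gene`: TE copies of the four main superfamilies inside/outside
#'   genes, by species and social level;
#' * `te_deg`: within-gene TE copies by superfamily, species, social
#'   level and host-gene bias class.
#'
#' Genes (and TEs hosted by genes) with an `untested` bias class are
#' excluded from the bias-stratified tables.
#'
#' @param profiles row-bound [profile_genes()] output with a `species`
#'   column.
#' @param tes_annot row-bound [annotate_tes()] output with a `species`
#'   column.
#' @param species_meta data frame `species, social_level`
#'   (`gregarious`/`eusocial`).
#' @return named list of four data frames, each ending in a `count`
#'   column.
#' @export
build_tables <- function(profiles, tes_annot, species_meta) {
  stopifnot(all(c("species", "social_level") %in% names(species_meta)))
  soc <- function(df) species_meta$social_level[match(df$species,
                                                      species_meta$species)]
  agg <- function(df, keys) {
    if (!nrow(df))
      return(cbind(df[keys], data.frame(count = integer())))
    stats::aggregate(list(count = df[[keys[1]]]), by = df[keys],
                     FUN = length)
  }
  fill <- function(counts, grid, keys) {
    i <- match(do.call(paste, grid[keys]), do.call(paste, counts[keys]))
    grid$count <- ifelse(is.na(i), 0L, counts$count[i])
    grid
  }
  species <- species_meta$species

  p <- profiles[!is.na(profiles$bias_class) &
                  profiles$bias_class != "untested", , drop = FALSE]
  p$social_level <- soc(p)
  p$te_overlap <- ifelse(p$n_te > 0, "yes", "no")
  cnt <- agg(p, c("species", "social_level", "bias_class", "te_overlap"))
  grid <- merge(expand.grid(bias_class = BIAS_CLASSES,
                            te_overlap = c("no", "yes"),
                            species = species,
                            stringsAsFactors = FALSE), species_meta)
  gene_te <- fill(cnt, grid, c("species", "bias_class", "te_overlap"))

  pw <- p[p$n_te > 0, , drop = FALSE]
  pw$feature <- ifelse(pw$n_exonic > 0, "exon", "intron")
  cnt <- agg(pw, c("species", "social_level", "bias_class", "feature"))
  grid <- merge(expand.grid(bias_class = BIAS_CLASSES,
                            feature = c("intron", "exon"),
                            species = species,
                            stringsAsFactors = FALSE), species_meta)
  gene_feature <- fill(cnt, grid, c("species", "bias_class", "feature"))

  t4 <- tes_annot[tes_annot$superfamily %in% SUPERFAMILIES, , drop = FALSE]
  t4$social_level <- soc(t4)
  t4$gene_overlap <- ifelse(t4$in_gene, "yes", "no")
  cnt <- agg(t4, c("species", "social_level", "superfamily",
                   "gene_overlap"))
  grid <- merge(expand.grid(superfamily = SUPERFAMILIES,
                            gene_overlap = c("no", "yes"),
                            species = species,
                            stringsAsFactors = FALSE), species_meta)
  te_gene <- fill(cnt, grid, c("species", "superfamily", "gene_overlap"))

  td <- t4[t4$in_gene & !is.na(t4$gene_bias) &
             t4$gene_bias != "untested", , drop = FALSE]
  cnt <- agg(td, c("species", "social_level", "superfamily", "gene_bias"))
  grid <- merge(expand.grid(superfamily = SUPERFAMILIES,
                            gene_bias = BIAS_CLASSES,
                            species = species,
                            stringsAsFactors = FALSE), species_meta)
  te_deg <- fill(cnt, grid, c("species", "superfamily", "gene_bias"))

  lapply(list(gene_te = gene_te, gene_feature = gene_feature,
              te_gene = te_gene, te_deg = te_deg), function(d) {
    d <- d[do.call(order, d[setdiff(names(d), "count")]), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

#' Mean gene length with 95% confidence interval per group
#'
#' Summarizes gene body length by grouping columns, with a Student-t 95%
#' confidence interval on the mean. Groups with a single gene get `NA`
#' bounds and `degenerate = TRUE`.
#'
#' @param profiles [profile_genes()] output (optionally with extra
#'   grouping columns such as `species`).
#' @param by character vector of grouping column names.
#' @return data frame with group columns, `n, mean_length, ci_low,
#'   ci_high, degenerate`.
#' @export
summarize_gene_length <- function(profiles, by = "bias_class") {
  stopifnot(all(by %in% names(profiles)))
  split_keys <- interaction(profiles[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(seq_len(nrow(profiles)), split_keys),
                               function(i) {
    len <- profiles$gene_length[i]
    n <- length(len)
    m <- mean(len)
    if (n > 1) {
      half <- stats::qt(0.975, n - 1) * stats::sd(len) / sqrt(n)
      data.frame(profiles[i[1], by, drop = FALSE], n = n, mean_length = m,
                 ci_low = m - half, ci_high = m + half, degenerate = FALSE)
    } else {
      data.frame(profiles[i[1], by, drop = FALSE], n = n, mean_length = m,
                 ci_low = NA_real_, ci_high = NA_real_, degenerate = TRUE)
    }
  }))
  rownames(out) <- NULL
  out
}
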