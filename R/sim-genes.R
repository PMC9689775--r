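#' Simulate gene models
#'
#' Places `n_genes` non-overlapping multi-exon genes on the simulated
#' chromosomes. Exon and intron counts/lengths are drawn uniformly from
#' the configured ranges; strands are assigned at random. Coordinates are
#' 1-based inclusive (the GFF3 convention used throughout the package).
#'
#' @param config a [sim_config()] object.
#' @return an object of class `gene_models`: a list with data frames
#'   `genes` (`chrom,start,end,strand,gene_id`), `exons`
#'   (`chrom,start,end,strand,gene_id,exon_id`) and `seqinfo`
#'   (`chrom,length`).
#' @examples
#' gm <- simulate_gene_models(sim_config(seed = 1, n_genes = 20,
#'                                       chrom_length = 5e5, n_chroms = 2))
#' nrow(gm$genes)
#' @export
simulate_gene_models <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genes"))
  chroms <- sprintf("chr%d", seq_len(config$n_chroms))
  seqinfo <- data.frame(chrom = chroms,
                        length = rep(config$chrom_length, config$n_chroms))
  empty <- gene_models(
    genes = data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       gene_id = character()),
    exons = data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(),
                       gene_id = character(), exon_id = character()),
    seqinfo = seqinfo)
  if (config$n_genes == 0L) return(empty)

  # draw per-gene structure first, then place whole gene bodies
  n <- config$n_genes
  n_ex <- sample_range(n, config$exon_count_range)
  structures <- lapply(seq_len(n), function(i) {
    k <- n_ex[i]
    ex_len <- sample_range(k, config$exon_length_range)
    in_len <- if (k > 1) sample_range(k - 1, config$intron_length_range)
              else integer()
    list(ex_len = ex_len, in_len = in_len,
         total = sum(ex_len) + sum(in_len))
  })
  totals <- vapply(structures, `[[`, numeric(1), "total")
  if (sum(totals) > config$n_chroms * config$chrom_length)
    stop("genome too small: total gene length exceeds genome size")

  # greedy chromosome assignment with bounded retries
  assignment <- NULL
  for (try in 1:25) {
    free <- rep(config$chrom_length, config$n_chroms)
    asg <- integer(n)
    ok <- TRUE
    for (i in sample.int(n)) {
      fits <- which(free >= totals[i])
      if (!length(fits)) { ok <- FALSE; break }
      pick <- if (length(fits) == 1L) fits else sample(fits, 1L)
      asg[i] <- pick
      free[pick] <- free[pick] - totals[i]
    }
    if (ok) { assignment <- asg; break }
  }
  if (is.null(assignment))
    stop("genome too small: could not place all genes after bounded retries")

  genes <- vector("list", n)
  exons <- vector("list", n)
  idx <- 0L
  for (ci in seq_len(config$n_chroms)) {
    gi <- which(assignment == ci)
    if (!length(gi)) next
    gi <- gi[order(stats::runif(length(gi)))]   # shuffle placement order
    slack <- config$chrom_length - sum(totals[gi])
    # random gaps: split the slack among n_gi + 1 interstices
    cuts <- sort(sample.int(slack + 1L, length(gi), replace = TRUE) - 1L)
    pos <- 1L
    prev_cut <- 0L
    for (j in seq_along(gi)) {
      g <- gi[j]
      pos <- pos + (cuts[j] - prev_cut)
      prev_cut <- cuts[j]
      idx <- idx + 1L
      st <- structures[[g]]
      gene_id <- sprintf("gene%05d", g)
      strand <- sample(c("+", "-"), 1L)
      ex_start <- pos + cumsum(c(0L, head(st$ex_len, -1) +
                                   if (length(st$in_len)) st$in_len else integer()))
      ex_end <- ex_start + st$ex_len - 1L
      genes[[idx]] <- data.frame(chrom = seqinfo$chrom[ci], start = pos,
                                 end = pos + st$total - 1L, strand = strand,
                                 gene_id = gene_id)
      exons[[idx]] <- data.frame(chrom = seqinfo$chrom[ci], start = ex_start,
                                 end = ex_end, strand = strand,
                                 gene_id = gene_id,
                                 exon_id = sprintf("%s.e%d", gene_id,
                                                   seq_along(ex_start)))
      pos <- pos + st$total
    }
  }
  genes <- do.call(rbind, genes[seq_len(idx)])
  exons <- do.call(rbind, exons[seq_len(idx)])
  o <- order(genes$chrom, genes$start)
  genes <- genes[o, , drop = FALSE]
  exons <- exons[order(exons$chrom, exons$start), , drop = FALSE]
  rownames(genes) <- rownames(exons) <- NULL
  gene_models(genes = genes, exons = exons, seqinfo = seqinfo)
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Construct a gene_models object
#'
#' Low-level constructor used by the simulator and the GFF3 reader.
#' Validates that exons nest within their parent gene span and share its
#' strand, and that gene bodies do not overlap on a chromosome.
#'
#' @param genes data frame with `chrom,start,end,strand,gene_id`.
#' @param exons data frame with `chrom,start,end,strand,gene_id,exon_id`.
#' @param seqinfo data frame with `chrom,length` (optional lengths).
#' @return a `gene_models` object.
#' @export
gene_models <- function(genes, exons, seqinfo = NULL) {
  req <- c("chrom", "start", "end", "strand", "gene_id")
  stopifnot(all(req %in% names(genes)), all(req %in% names(exons)))
  if (nrow(genes)) {
    if (any(genes$end < genes$start)) stop("gene with end < start")
    span <- genes[match(exons$gene_id, genes$gene_id), ]
    if (any(is.na(span$start))) stop("exon with unknown parent gene")
    if (any(exons$start < span$start | exons$end > span$end))
      stop("exon outside parent gene span")
    if (any(exons$strand != span$strand))
      stop("exon strand differs from parent gene")
  }
  if (is.null(seqinfo))
    seqinfo <- data.frame(chrom = unique(genes$chrom),
                          length = NA_real_)
  structure(list(genes = genes, exons = exons, seqinfo = seqinfo),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models>", nrow(x$genes), "genes,", nrow(x$exons), "exons on",
      nrow(x$seqinfo), "sequences\n")
  invisible(x)
}

#' Gene lengths in bp
#' @param models a `gene_models` object.
#' @return named numeric vector of gene body lengths.
#' @export
gene_lengths <- function(models) {
  stats::setNames(models$genes$end - models$genes$start + 1,
                  models$genes$gene_id)
}
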