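#' Simulate multi-tool TE call sets with planted truth
#'
#' Plants "true" TE insertions of the four main superfamilies
#' (Tc-Mariner, hAT, Gypsy, LINE) across the genome at `te_density`
#' insertions per Mb per superfamily, then emulates a panel of annotation
#' tools: each true TE is reported by one primary tool and re-reported by
#' each additional tool with probability `redundancy` (boundaries
#' jittered by `jitter_sd` bp); each tool also adds a fraction `fp_rate`
#' of spurious calls. A mapped-copy set with RepeatMasker-style scores is
#' generated alongside, including low-score junk and overlapping
#' lower-score duplicates for the downstream filters to remove.
#'
#' Per-class insertion multipliers (`te_bias_mult`) plant extra
#' insertions inside (or thin insertions from) genes of a given
#' expression-bias class, which is how opposite termite-vs-cockroach
#' insertion trends are simulated.
#'
#' @param models a `gene_models` object.
#' @param config a [sim_config()] object.
#' @param gene_class optional named character vector (gene_id ->
#'   bias class) used with `config$te_bias_mult`.
#' @return a list with `callsets` (named list of per-tool call data
#'   frames: `chrom,start,end,strand,tool,superfamily,score`), `mapped`
#'   (mapped-copy data frame: `chrom,start,end,strand,superfamily,score,
#'   copy_id,true_te`), and `truth` (planted TE table).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 20, n_chroms = 1,
#'                   chrom_length = 5e5, te_density = 20)
#' sim <- simulate_te_callsets(simulate_gene_models(cfg), cfg)
#' names(sim$callsets)
#' @export
simulate_te_callsets <- function(models, config, gene_class = NULL) {
  stopifnot(inherits(config, "sim_config"), config$n_tools >= 1L)
  set.seed(stage_seed(config$seed, "te"))
  si <- models$seqinfo
  genome_mb <- sum(si$length) / 1e6

  truth <- list()
  for (sf in SUPERFAMILIES) {
    n_base <- stats::rpois(1, config$te_density * genome_mb)
    if (n_base == 0) next
    len <- sample_range(n_base, config$te_length_range)
    chrom_i <- sample(seq_len(nrow(si)), n_base, replace = TRUE,
                      prob = si$length)
    start <- floor(stats::runif(n_base, 1, si$length[chrom_i] - len + 1))
    truth[[sf]] <- data.frame(chrom = si$chrom[chrom_i],
                              start = as.integer(start),
                              end = as.integer(start + len - 1L),
                              strand = sample(c("+", "-"), n_base, TRUE),
                              superfamily = sf)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), superfamily = character())

  # class-specific planting: thin classes with mult < 1, add extra
  # insertions inside genes of classes with mult > 1
  if (!is.null(gene_class) && nrow(models$genes)) {
    g <- models$genes
    g$class <- unname(gene_class[g$gene_id])
    host <- host_gene(truth, g)
    mult <- config$te_bias_mult
    keep <- rep(TRUE, nrow(truth))
    for (cl in names(mult)) {
      m <- mult[[cl]]
      in_cl <- !is.na(host) & !is.na(g$class[host]) & g$class[host] == cl
      if (m < 1 && any(in_cl))
        keep[in_cl] <- stats::runif(sum(in_cl)) < m
      if (m > 1) {
        gi <- which(!is.na(g$class) & g$class == cl)
        if (length(gi)) {
          class_mb <- sum(g$end[gi] - g$start[gi] + 1) / 1e6
          n_extra <- stats::rpois(1, config$te_density * class_mb * (m - 1) *
                                    length(SUPERFAMILIES))
          if (n_extra > 0) {
            pick <- sample(gi, n_extra, replace = TRUE,
                           prob = g$end[gi] - g$start[gi] + 1)
            len <- sample_range(n_extra, config$te_length_range)
            glen <- g$end[pick] - g$start[pick] + 1
            len <- pmin(len, glen)
            st <- g$start[pick] +
              floor(stats::runif(n_extra) * (glen - len + 1))
            truth <- rbind(truth[keep, , drop = FALSE],
                           data.frame(chrom = g$chrom[pick],
                                      start = as.integer(st),
                                      end = as.integer(st + len - 1L),
                                      strand = sample(c("+", "-"), n_extra, TRUE),
                                      superfamily = sample(SUPERFAMILIES,
                                                           n_extra, TRUE)))
            keep <- rep(TRUE, nrow(truth))
          }
        }
      }
    }
    truth <- truth[keep, , drop = FALSE]
  }
  if (nrow(truth)) {
    truth <- truth[order(truth$chrom, truth$start, truth$end), , drop = FALSE]
    truth$te_id <- sprintf("TE%06d", seq_len(nrow(truth)))
    rownames(truth) <- NULL
  } else truth$te_id <- character()

  tools <- sprintf("tool%02d", seq_len(config$n_tools))
  n_true <- nrow(truth)
  callsets <- list()
  primary <- if (n_true) sample(seq_len(config$n_tools), n_true, TRUE) else
    integer()
  for (ti in seq_len(config$n_tools)) {
    rep_by <- if (n_true) {
      primary == ti | stats::runif(n_true) < config$redundancy
    } else logical()
    calls <- truth[rep_by, c("chrom", "start", "end", "strand",
                             "superfamily", "te_id"), drop = FALSE]
    if (nrow(calls) && config$jitter_sd > 0 && any(primary[rep_by] != ti)) {
      jit <- primary[rep_by] != ti   # re-reports get jittered boundaries
      nj <- sum(jit)
      calls$start[jit] <- pmax(1L, as.integer(round(
        calls$start[jit] + stats::rnorm(nj, 0, config$jitter_sd))))
      calls$end[jit] <- pmax(calls$start[jit] + 1L, as.integer(round(
        calls$end[jit] + stats::rnorm(nj, 0, config$jitter_sd))))
    }
    n_fp <- round(config$fp_rate * nrow(calls))
    if (n_fp > 0) {
      len <- sample_range(n_fp, config$te_length_range)
      chrom_i <- sample(seq_len(nrow(si)), n_fp, replace = TRUE,
                        prob = si$length)
      st <- floor(stats::runif(n_fp, 1, si$length[chrom_i] - len + 1))
      calls <- rbind(calls,
                     data.frame(chrom = si$chrom[chrom_i],
                                start = as.integer(st),
                                end = as.integer(st + len - 1L),
                                strand = sample(c("+", "-"), n_fp, TRUE),
                                superfamily = sample(SUPERFAMILIES, n_fp, TRUE),
                                te_id = NA_character_))
    }
    calls$tool <- tools[ti]
    calls$score <- round(stats::runif(nrow(calls), 50, 5000))
    rownames(calls) <- NULL
    callsets[[tools[ti]]] <- calls[, c("chrom", "start", "end", "strand",
                                       "tool", "superfamily", "score",
                                       "te_id")]
  }

  # mapped copies: true TEs with RepeatMasker-style scores + removable junk
  mapped <- truth[, c("chrom", "start", "end", "strand", "superfamily"),
                  drop = FALSE]
  mapped$score <- round(stats::runif(nrow(mapped), 50, 5000))
  mapped$true_te <- TRUE
  if (n_true) {
    n_dup <- max(0L, round(0.10 * n_true))
    dup <- if (n_dup) sample(seq_len(n_true), n_dup) else integer()
    if (length(dup)) {
      shift <- as.integer(round(stats::runif(n_dup, 10, 100)))
      dups <- mapped[dup, , drop = FALSE]
      dups$start <- pmax(1L, dups$start + shift)
      dups$end <- pmax(dups$start + 1L, dups$end + shift)
      dups$score <- pmax(2, round(dups$score * stats::runif(n_dup, 0.2, 0.8)))
      dups$true_te <- FALSE
      mapped <- rbind(mapped, dups)
    }
    n_junk <- max(0L, round(0.05 * n_true))
    if (n_junk) {
      len <- sample_range(n_junk, config$te_length_range)
      chrom_i <- sample(seq_len(nrow(si)), n_junk, replace = TRUE,
                        prob = si$length)
      st <- floor(stats::runif(n_junk, 1, si$length[chrom_i] - len + 1))
      mapped <- rbind(mapped,
                      data.frame(chrom = si$chrom[chrom_i],
                                 start = as.integer(st),
                                 end = as.integer(st + len - 1L),
                                 strand = sample(c("+", "-"), n_junk, TRUE),
                                 superfamily = sample(SUPERFAMILIES, n_junk,
                                                      TRUE),
                                 score = sample(0:1, n_junk, TRUE),
                                 true_te = FALSE))
    }
  }
  mapped <- mapped[order(mapped$chrom, mapped$start, mapped$end), ,
                   drop = FALSE]
  mapped$copy_id <- sprintf("copy%06d", seq_len(nrow(mapped)))
  rownames(mapped) <- NULL

  list(callsets = callsets, mapped = mapped, truth = truth)
}

# index of the gene whose span contains the TE midpoint (NA if intergenic)
host_gene <- function(te, genes) {
  if (!nrow(te) || !nrow(genes)) return(rep(NA_integer_, nrow(te)))
  mid <- (te$start + te$end) %/% 2
  gr_t <- GenomicRanges::GRanges(te$chrom, IRanges::IRanges(mid, mid))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  hit <- GenomicRanges::findOverlaps(gr_t, gr_g, select = "first")
  as.integer(hit)
}
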