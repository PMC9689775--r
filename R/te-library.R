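#' Deduplicate multi-tool TE calls
#'
#' Consolidates the combined call sets of several de novo TE annotation
#' tools into a non-redundant library: calls longer than `max_len` are
#' removed first, then calls are swept greedily in priority order (longer
#' call first; ties by earlier start, then lexicographic tool id) and a
#' call is dropped when it overlaps an already-retained call on the same
#' chromosome and strand by more than `max_overlap_frac` of the shorter
#' of the two lengths. Opposite-strand overlaps never conflict (strand is
#' part of the element's identity).
#'
#' The procedure is deterministic, idempotent, and invariant to the input
#' row order.
#'
#' @param calls data frame with `chrom,start,end,strand,tool` (1-based
#'   inclusive; `superfamily`/`score` columns are carried through).
#' @param max_overlap_frac maximum tolerated overlap fraction, relative
#'   to the shorter call.
#' @param max_len maximum retained call length in bp.
#' @return the retained subset of `calls`, sorted by position.
#' @examples
#' calls <- data.frame(chrom = "chr1", start = c(1, 51), end = c(100, 150),
#'                     strand = "+", tool = c("a", "b"))
#' dedup_calls(calls)  # 50% overlap: only the first is kept
#' @export
dedup_calls <- function(calls, max_overlap_frac = 0.20, max_len = 10000) {
  stopifnot(max_overlap_frac >= 0, max_overlap_frac <= 1)
  req <- c("chrom", "start", "end", "strand", "tool")
  if (!all(req %in% names(calls)))
    stop("calls must have columns ", paste(req, collapse = ", "))
  bad <- which(calls$end < calls$start)
  if (length(bad))
    stop("malformed interval (start > end) at row ", bad[1], ": ",
         calls$chrom[bad[1]], ":", calls$start[bad[1]], "-",
         calls$end[bad[1]])
  if (!nrow(calls)) return(calls)

  len <- calls$end - calls$start + 1
  calls <- calls[len <= max_len, , drop = FALSE]   # length filter first
  if (!nrow(calls)) return(calls)
  len <- calls$end - calls$start + 1

  ord <- order(-len, calls$start, calls$tool, calls$chrom, calls$end)
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end),
                               strand = calls$strand)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                      ignore.strand = FALSE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- pmin(calls$end[qh], calls$end[sh]) -
    pmax(calls$start[qh], calls$start[sh]) + 1
  frac <- ov / pmin(len[qh], len[sh])
  conflict <- frac > max_overlap_frac
  adj <- split(sh[conflict], factor(qh[conflict], levels = seq_len(nrow(calls))))

  kept <- logical(nrow(calls))
  for (i in ord) {
    if (!any(kept[adj[[i]]])) kept[i] <- TRUE
  }
  out <- calls[kept, , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end, out$tool), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter mapped TE copies by score and overlap
#'
#' Applies the mapped-copy quality rules: copies with a mapping score not
#' greater than `min_score_exclusive` are removed as low quality, and
#' within any chain of location-overlapping copies (same chromosome, any
#' strand -- mapped copies compete for the same genomic space) only the
#' copy with the highest score is retained; score ties keep the earlier
#' start, then the lexicographically first `copy_id`.
#'
#' @param copies data frame with `chrom,start,end,strand,score` and
#'   optionally `copy_id`.
#' @param min_score_exclusive retained copies must have score strictly
#'   greater than this.
#' @return the retained subset, sorted by position.
#' @examples
#' m <- data.frame(chrom = "chr1", start = c(1, 50), end = c(120, 170),
#'                 strand = c("+", "-"), score = c(5, 3),
#'                 copy_id = c("a", "b"))
#' filter_mapped(m)  # overlapping: only the score-5 copy survives
#' @export
filter_mapped <- function(copies, min_score_exclusive = 1) {
  req <- c("chrom", "start", "end", "strand", "score")
  if (!all(req %in% names(copies)))
    stop("copies must have columns ", paste(req, collapse = ", "))
  if (anyNA(copies$score)) stop("missing mapping score")
  if (!nrow(copies)) return(copies)
  if (!"copy_id" %in% names(copies))
    copies$copy_id <- sprintf("row%d", seq_len(nrow(copies)))

  copies <- copies[copies$score > min_score_exclusive, , drop = FALSE]
  if (!nrow(copies)) return(copies)
  gr <- GenomicRanges::GRanges(copies$chrom,
                               IRanges::IRanges(copies$start, copies$end))
  # connected chains of >=1 bp overlap = blocks of the reduced ranges
  blocks <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  member <- GenomicRanges::findOverlaps(gr, blocks, select = "first",
                                        ignore.strand = TRUE)
  ord <- order(member, -copies$score, copies$start, copies$copy_id)
  best <- ord[!duplicated(member[ord])]
  out <- copies[sort(best), , drop = FALSE]
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}
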