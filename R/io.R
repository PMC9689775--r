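#' Write gene models to GFF3
#'
#' Emits a deterministic GFF3 file (1-based inclusive coordinates) with
#' `gene` and `exon` features, `ID` and `Parent` attributes, and
#' `##sequence-region` pragmas from the seqinfo table. Output is
#' byte-stable for a given `gene_models` object.
#'
#' @param models a `gene_models` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  con <- file(path, open = "wb")  # binary: stable newlines across platforms
  on.exit(close(con))
  put <- function(lines) writeLines(lines, con, sep = "\n")
  put("##gff-version 3")
  si <- models$seqinfo
  if (nrow(si) && !all(is.na(si$length)))
    put(sprintf("##sequence-region %s 1 %d", si$chrom, as.integer(si$length)))
  g <- models$genes
  if (nrow(g)) {
    put(sprintf("%s\tcasteTE\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$chrom, as.integer(g$start), as.integer(g$end), g$strand,
                g$gene_id))
    e <- models$exons
    put(sprintf("%s\tcasteTE\texon\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                e$chrom, as.integer(e$start), as.integer(e$end), e$strand,
                e$exon_id, e$gene_id))
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` features with `rtracklayer` and rebuilds a
#' `gene_models` object. Exons are matched to genes via their `Parent`
#' attribute.
#'
#' @param path GFF3 file.
#' @return a `gene_models` object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   type = as.character(gr$type),
                   id = as.character(gr$ID))
  parent <- as.character(S4Vectors::mcols(gr)$Parent)
  genes <- df[df$type == "gene", c("chrom", "start", "end", "strand", "id")]
  names(genes)[5] <- "gene_id"
  ex <- df$type == "exon"
  exons <- df[ex, c("chrom", "start", "end", "strand", "id")]
  names(exons)[5] <- "exon_id"
  exons$gene_id <- parent[ex]
  exons <- exons[, c("chrom", "start", "end", "strand", "gene_id", "exon_id")]
  rownames(genes) <- rownames(exons) <- NULL
  gene_models(genes = genes, exons = exons)
}

#' Write TE intervals as BED6+2
#'
#' Columns: chrom, start (0-based), end (half-open), name, score, strand,
#' superfamily, and one extra identifier column. Internal 1-based
#' inclusive coordinates are converted to the BED convention on write.
#'
#' @param te data frame with `chrom,start,end,strand,superfamily,score`
#'   plus the columns named by `name_col` / `extra_col`.
#' @param path output file path.
#' @param name_col column used for the BED name field (e.g. `tool` for
#'   raw call sets, `copy_id` for mapped copies).
#' @param extra_col column written as the 8th field (default the same
#'   identifier again when absent).
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(te, path, name_col = "tool", extra_col = name_col) {
  stopifnot(all(c("chrom", "start", "end", "strand", "superfamily",
                  "score", name_col) %in% names(te)))
  out <- data.frame(chrom = te$chrom,
                    start = as.integer(te$start) - 1L,
                    end = as.integer(te$end),
                    name = te[[name_col]],
                    score = te$score,
                    strand = te$strand,
                    superfamily = te$superfamily,
                    extra = te[[extra_col]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(do.call(sprintf, c(list("%s\t%d\t%d\t%s\t%g\t%s\t%s\t%s"),
                                unname(as.list(out)))), con, sep = "\n")
  invisible(path)
}

#' Read TE intervals from BED6+2
#'
#' @param path BED6+2 file as written by [write_te_bed()].
#' @param name_col name to give the BED name column on read.
#' @param extra_col name to give the 8th column on read.
#' @return data frame with 1-based inclusive `start`/`end`.
#' @export
read_te_bed <- function(path, name_col = "tool", extra_col = "id") {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", name_col,
                                        "score", "strand", "superfamily",
                                        extra_col),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character",
                                         "character", "character"))
  df$start <- df$start + 1L
  df
}

#' Write/read tab-separated tables
#'
#' Thin deterministic wrappers around [utils::write.table()] /
#' [utils::read.table()] used for count matrices, sample sheets, GO maps
#' and truth tables.
#'
#' @param x data frame (or matrix with row names for `row_names = TRUE`).
#' @param path file path.
#' @param row_names write/read a leading row-name column.
#' @return `write_tsv`: `path` invisibly; `read_tsv`: a data frame.
#' @export
write_tsv <- function(x, path, row_names = FALSE) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = row_names,
                     col.names = if (row_names) NA else TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path, row_names = FALSE) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    row.names = if (row_names) 1L else NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
}
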